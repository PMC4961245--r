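#' Read a neuron skeleton from an SWC file
#'
#' Parses the standard whitespace-delimited 7-column SWC format
#' (`node_id structure x y z radius parent_id`). Lines starting with `#`
#' and blank lines are ignored. Coordinates are taken to be micrometers in a
#' registered template space; no unit conversion is attempted. Node ids need
#' not be contiguous or sorted. A file may contain several trees (several
#' nodes with `parent_id = -1`); the node table must describe a forest.
#'
#' @param path Path to an SWC file.
#' @return A `neuron_skeleton`: a data frame with columns `node_id`,
#'   `structure`, `x`, `y`, `z`, `radius`, `parent_id`, in file order.
#' @seealso [write_swc()], [skeleton_to_dotprops()]
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    stop("no data lines in SWC file: ", path)
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(fields, length, 1L) != 7L)
  if (length(bad))
    stop(sprintf("malformed SWC line %d in %s: expected 7 fields",
                 lineno[bad[1L]], path))
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 7L, byrow = TRUE)
  nn <- which(apply(is.na(m), 1L, any))
  if (length(nn))
    stop(sprintf("malformed SWC line %d in %s: non-numeric field",
                 lineno[nn[1L]], path))
  skel <- data.frame(node_id = as.integer(m[, 1L]),
                     structure = as.integer(m[, 2L]),
                     x = m[, 3L], y = m[, 4L], z = m[, 5L],
                     radius = m[, 6L],
                     parent_id = as.integer(m[, 7L]))
  class(skel) <- c("neuron_skeleton", "data.frame")
  validate_skeleton(skel)
  skel
}

#' Validate skeleton invariants
#'
#' Checks that node ids are unique, every non-root parent id refers to an
#' existing node, and the parent graph is a forest (no cycles, at least one
#' root).
#'
#' @param skel A `neuron_skeleton` data frame.
#' @return The skeleton, invisibly. Errors on violation.
#' @export
validate_skeleton <- function(skel) {
  need <- c("node_id", "parent_id", "x", "y", "z")
  if (!all(need %in% names(skel)))
    stop("skeleton lacks required columns: ",
         paste(setdiff(need, names(skel)), collapse = ", "))
  if (nrow(skel) == 0L) stop("empty skeleton")
  if (anyDuplicated(skel$node_id))
    stop("duplicate node_id in skeleton")
  root <- skel$parent_id == -1L
  if (!any(root)) stop("skeleton has no root node (parent_id -1)")
  dangling <- !root & !(skel$parent_id %in% skel$node_id)
  if (any(dangling))
    stop("node ", skel$node_id[which(dangling)[1L]],
         " has parent_id ", skel$parent_id[which(dangling)[1L]],
         " which does not exist")
  # forest check: follow parents; every node must reach a root without
  # revisiting itself
  parent_of <- match(skel$parent_id, skel$node_id)  # NA at roots
  depth <- rep(NA_integer_, nrow(skel))
  depth[root] <- 0L
  for (i in seq_len(nrow(skel))) {
    if (!is.na(depth[i])) next
    chain <- i
    j <- i
    repeat {
      j <- parent_of[j]
      if (is.na(j)) { d <- 0L; break }       # reached a root
      if (!is.na(depth[j])) { d <- depth[j]; break }
      if (j %in% chain) stop("cycle detected in skeleton parent graph")
      chain <- c(chain, j)
    }
    depth[rev(chain)] <- d + seq_along(chain)
  }
  invisible(skel)
}

#' Write a neuron skeleton to an SWC file
#'
#' Coordinates and radii are written with 17 significant digits so that
#' `read_swc(write_swc(s))` reproduces node ids, topology and coordinates to
#' full double precision.
#'
#' @param skel A valid `neuron_skeleton`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(skel, path) {
  validate_skeleton(skel)
  rad <- if ("radius" %in% names(skel)) skel$radius else rep(1, nrow(skel))
  strc <- if ("structure" %in% names(skel)) skel$structure else
    rep(0L, nrow(skel))
  lines <- sprintf("%d %d %.17g %.17g %.17g %.17g %d",
                   skel$node_id, strc, skel$x, skel$y, skel$z, rad,
                   skel$parent_id)
  writeLines(lines, path)
  invisible(path)
}

#' Write a scoring matrix as human-readable delimited text
#'
#' The layout mirrors the matrix itself: a header row with the dot-product
#' bin boundaries, then one row per distance bin starting with the bin's
#' lower and upper distance boundary (micrometers) followed by the log2-odds
#' cell values. Epsilon and provenance are kept on `#` comment lines. All
#' numbers use 17 significant digits, so a text round trip is lossless.
#'
#' @param smat A [scoring_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_scoring_matrix()]
#' @export
write_scoring_matrix <- function(smat, path) {
  stopifnot(inherits(smat, "scoring_matrix"))
  g <- function(x) sprintf("%.17g", x)
  nd <- length(smat$dist_breaks) - 1L
  lines <- c(
    sprintf("# epsilon: %.17g", smat$epsilon),
    sprintf("# provenance: %s", gsub("[\r\n]+", " ", smat$provenance)),
    paste(c("dot_breaks", g(smat$dot_breaks)), collapse = "\t"),
    vapply(seq_len(nd), function(i) {
      paste(c(g(smat$dist_breaks[i]), g(smat$dist_breaks[i + 1L]),
              g(smat$values[i, ])), collapse = "\t")
    }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a scoring matrix written by [write_scoring_matrix()]
#'
#' @param path Path to a scoring-matrix text file.
#' @return A [scoring_matrix()].
#' @export
read_scoring_matrix <- function(path) {
  lines <- readLines(path)
  eps <- 1e-6
  prov <- ""
  m <- regmatches(lines, regexec("^# epsilon: (.*)$", lines))
  for (mm in m) if (length(mm)) eps <- as.numeric(mm[2L])
  m <- regmatches(lines, regexec("^# provenance: (.*)$", lines))
  for (mm in m) if (length(mm)) prov <- mm[2L]
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("scoring-matrix file too short: ", path)
  hdr <- strsplit(lines[1L], "\t")[[1L]]
  if (hdr[1L] != "dot_breaks")
    stop("scoring-matrix file lacks dot_breaks header: ", path)
  dot_breaks <- as.numeric(hdr[-1L])
  body <- strsplit(lines[-1L], "\t")
  ncell <- length(dot_breaks) - 1L
  if (any(vapply(body, length, 1L) != ncell + 2L))
    stop("scoring-matrix row length inconsistent with dot_breaks in ", path)
  body <- matrix(as.numeric(unlist(body)), ncol = ncell + 2L, byrow = TRUE)
  lo <- body[, 1L]
  hi <- body[, 2L]
  if (nrow(body) > 1L && any(hi[-nrow(body)] != lo[-1L]))
    stop("distance bin boundaries are not contiguous in ", path)
  smat <- scoring_matrix(values = body[, -(1:2), drop = FALSE],
                         dist_breaks = c(lo, hi[length(hi)]),
                         dot_breaks = dot_breaks,
                         epsilon = eps, provenance = prov)
  if (!smat_max_at_origin(smat))
    warning("scoring matrix maximum is not at the best-match cell; ",
            "normalized scores may exceed 1 (sparsely trained matrix?)")
  smat
}

#' Write a score table to CSV
#'
#' One row per query neuron, one column per target neuron, labelled with the
#' neuron ids; readable by any CSV parser.
#'
#' @param table A [score_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path) {
  stopifnot(inherits(table, "score_table"))
  v <- table$values
  if (anyDuplicated(rownames(v)) || anyDuplicated(colnames(v)))
    stop("duplicate query or target labels in score table")
  ch <- matrix(sprintf("%.17g", v), nrow = nrow(v),
               dimnames = dimnames(v))
  df <- data.frame(id = rownames(v), ch, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a score table written by [write_score_table()]
#'
#' @param path CSV path.
#' @param normalization The normalization the stored scores were computed
#'   under (`"raw"`, `"normalized"` or `"mean"`); the CSV itself does not
#'   record it.
#' @return A [score_table()].
#' @export
read_score_table <- function(path, normalization = "raw") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 1L) stop("empty score-table CSV: ", path)
  v <- as.matrix(df[, -1L, drop = FALSE])
  mode(v) <- "numeric"
  rownames(v) <- df[[1L]]
  score_table(v, normalization = normalization)
}

#' Write dotprops to CSV (x,y,z,vx,vy,vz)
#'
#' @param dp A [dotprops()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dotprops_csv <- function(dp, path) {
  stopifnot(inherits(dp, "dotprops"))
  g <- function(x) sprintf("%.17g", x)
  df <- data.frame(x = g(dp$points[, 1L]), y = g(dp$points[, 2L]),
                   z = g(dp$points[, 3L]),
                   vx = g(dp$vect[, 1L]), vy = g(dp$vect[, 2L]),
                   vz = g(dp$vect[, 3L]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read dotprops from a CSV of x,y,z,vx,vy,vz
#'
#' @param path CSV path.
#' @param label Identifier for the loaded neuron; defaults to the file name.
#' @return A [dotprops()] object.
#' @export
read_dotprops_csv <- function(path, label = NULL) {
  df <- utils::read.csv(path)
  need <- c("x", "y", "z", "vx", "vy", "vz")
  if (!all(need %in% names(df)))
    stop("dotprops CSV must have columns x,y,z,vx,vy,vz: ", path)
  if (is.null(label))
    label <- sub("\\.[^.]*$", "", basename(path))
  dotprops(points = as.matrix(df[, c("x", "y", "z")]),
           vect = as.matrix(df[, c("vx", "vy", "vz")]),
           k = NA_integer_, label = label)
}
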