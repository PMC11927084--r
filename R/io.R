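#' Read an undirected edge list (SNAP dialect)
#'
#' Plain-text files with two whitespace-separated integer ids per line and
#' `#` comment lines. Arbitrary node ids are remapped to contiguous
#' internal ids `1..n` (the original-id order is preserved in the mapping
#' attribute). Duplicate and reversed pairs are collapsed; self loops are
#' dropped with a warning.
#'
#' @param path Path to the edge-list file.
#' @param mapping_path Optional path to also persist the id mapping as a
#'   CSV with header `original_id,internal_id`.
#' @return A `labeled_graph` (unlabelled) with attribute `id_map`, a data
#'   frame mapping original to internal ids.
#' @export
read_edgelist <- function(path, mapping_path = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(toks) != 2L)
  if (length(bad))
    stop(sprintf("malformed edge list line %d: '%s'", idx[bad[1L]],
                 lines[idx[bad[1L]]]))
  flat <- suppressWarnings(as.integer(unlist(toks)))
  if (anyNA(flat)) {
    bad <- idx[ceiling(which(is.na(flat))[1L] / 2)]
    stop(sprintf("malformed edge list line %d: non-integer id", bad))
  }
  a <- flat[c(TRUE, FALSE)]
  b <- flat[c(FALSE, TRUE)]
  loops <- a == b
  if (any(loops)) {
    warning(sprintf("dropping %d self loop(s)", sum(loops)))
    a <- a[!loops]; b <- b[!loops]
  }
  ids <- sort(unique(c(a, b)))
  ai <- match(a, ids)
  bi <- match(b, ids)
  g <- labeled_graph(length(ids), cbind(ai, bi))
  id_map <- data.frame(original_id = ids, internal_id = seq_along(ids))
  attr(g, "id_map") <- id_map
  if (!is.null(mapping_path))
    write.csv(id_map, mapping_path, row.names = FALSE, quote = FALSE)
  g
}

#' Write an undirected edge list (SNAP dialect)
#'
#' Each edge is written once. If the graph carries an `id_map` attribute
#' (from [read_edgelist()]) the original ids are used; otherwise the
#' 0-based internal ids are written.
#'
#' @param graph A `labeled_graph`.
#' @param path Output path.
#' @export
write_edgelist <- function(graph, path) {
  em <- edge_matrix(graph)
  id_map <- attr(graph, "id_map")
  if (!is.null(id_map)) {
    em[] <- id_map$original_id[em]
  } else {
    em <- em - 1L
  }
  writeLines(c("# undirected edge list", paste(em[, 1L], em[, 2L])), path)
}

node_table_io <- function(values, path, col) {
  df <- data.frame(node = seq_along(values) - 1L, v = values)
  names(df)[2L] <- col
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}

read_node_table <- function(path, col, n = NULL) {
  df <- read.csv(path)
  if (!all(c("node", col) %in% names(df)))
    stop(sprintf("expected CSV with header 'node,%s'", col))
  o <- order(df$node)
  v <- as.integer(df[[col]][o])
  node <- as.integer(df$node[o])
  if (!identical(node, seq_along(node) - 1L))
    stop("'node' column must be the contiguous 0-based ids 0..N-1")
  if (!is.null(n) && length(v) != n)
    stop("file has a different number of nodes than the graph")
  if (anyNA(v) || !all(v %in% c(0L, 1L)))
    stop(sprintf("'%s' values must be 0 or 1", col))
  v
}

#' Group-label and choice-state files
#'
#' CSV files with headers `node,group` (0 = blue, 1 = red) and
#' `node,choice`; node ids are 0-based and contiguous.
#'
#' @param group,choices Integer vector in `{0, 1}`.
#' @param path File path.
#' @param n Optional expected node count for validation.
#' @name label_io
NULL

#' @rdname label_io
#' @export
write_labels <- function(group, path) node_table_io(group, path, "group")

#' @rdname label_io
#' @export
read_labels <- function(path, n = NULL) read_node_table(path, "group", n)

#' @rdname label_io
#' @export
write_choices <- function(choices, path) node_table_io(choices, path, "choice")

#' @rdname label_io
#' @export
read_choices <- function(path, n = NULL) read_node_table(path, "choice", n)

#' Write a trajectory and its switching events to CSV
#'
#' The trajectory goes to `path` (columns `t`, `theta_B`, `theta_R` and,
#' for mean-field trajectories, `region_B`, `region_R`); switching events,
#' if present, go to a second file `<path-sans-ext>_events.csv`.
#'
#' @param traj A trajectory from [mf_integrate()] or [abm_run()].
#' @param path Output CSV path.
#' @return Invisibly, the paths written.
#' @export
write_trajectory <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE, quote = FALSE)
  paths <- path
  ev <- attr(traj, "events")
  if (!is.null(ev) && nrow(ev)) {
    evp <- sub("\\.csv$", "", path)
    evp <- paste0(evp, "_events.csv")
    write.csv(ev, evp, row.names = FALSE, quote = FALSE)
    paths <- c(paths, evp)
  }
  invisible(paths)
}

write_metadata <- function(meta, path) {
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
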