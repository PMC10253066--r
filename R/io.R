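#' Read / write the long-format per-cell table
#'
#' Tab-delimited table with columns \code{experiment, plate, variant,
#' condition, cell_id, hoechst, yp} — the interchange format produced by the
#' screen generator and the image quantifier and consumed by the
#' quantification pipeline.
#'
#' @param cells per-cell data.frame.
#' @param path file path.
#' @return \code{read_cell_table}: the data.frame;
#'   \code{write_cell_table}: the path, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.table(cells, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = list(experiment = "character",
                                           plate = "character",
                                           variant = "character"))
  need <- c("experiment", "plate", "variant", "condition", "yp")
  if (!all(need %in% names(d)))
    stop("cell table must have columns: ", paste(need, collapse = ", "))
  d
}

#' Write the ground-truth sidecar of a simulated screen
#'
#' @param screen an \code{"ep_screen"}.
#' @param path path for the per-variant truth table; the per-plate scale
#'   table goes to \code{<path>} with suffix \code{"_scales"} before the
#'   extension.
#' @return invisibly, the two paths written.
#' @export
write_ground_truth <- function(screen, path) {
  stopifnot(inherits(screen, "ep_screen"))
  utils::write.table(screen$truth$variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p2 <- sub("(\\.[^.]*)?$", "_scales\\1", path)
  utils::write.table(screen$truth$plate_scales, p2, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(path, p2))
}

#' Read / write a generator configuration as YAML
#'
#' Scalar fields are stored as keys; \code{effect_map} and
#' \code{editing_fraction} as named maps.
#'
#' @param cfg a \code{\link{screen_config}}.
#' @param path file path.
#' @return \code{read_screen_config}: a validated \code{screen_config};
#'   \code{write_screen_config}: the path, invisibly.
#' @export
write_screen_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "screen_config"))
  yaml::write_yaml(lapply(unclass(cfg), function(x)
    if (!is.null(names(x))) as.list(x) else x), path)
  invisible(path)
}

#' @rdname write_screen_config
#' @export
read_screen_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("effect_map", "editing_fraction"))
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  do.call(screen_config, raw[setdiff(names(raw), c())])
}

#' Read a T7EI lane table
#'
#' Tab- or comma-delimited with columns \code{lane, A, B, C, treated}.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return data.frame suitable for \code{\link{cleavage_table}}.
#' @export
read_lane_table <- function(path, sep = "\t") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("lane", "A", "B", "C", "treated")
  if (!all(need %in% names(d)))
    stop("lane table must have columns: ", paste(need, collapse = ", "))
  d$treated <- as.logical(d$treated)
  d
}

#' Read an expression panel from delimited tables
#'
#' @param expr_path gene x line expression table (first column = gene id,
#'   remaining columns = cell lines).
#' @param ld50_path two-column table \code{line, ld50}.
#' @param sep field separator (default tab).
#' @return an \code{\link{expression_panel}}.
#' @export
read_expression_panel <- function(expr_path, ld50_path, sep = "\t") {
  e <- utils::read.table(expr_path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(e[, -1, drop = FALSE])
  rownames(m) <- e[[1]]
  l <- utils::read.table(ld50_path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  expression_panel(m, stats::setNames(l[[2]], l[[1]]))
}
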