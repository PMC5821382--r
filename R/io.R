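#' @title Edge-list files and run manifests
#' @name lv_io
NULL

#' Write a topology as an edge-list CSV
#'
#' The file starts with a comment line `# S=<S> model=<tag> C_target=<C>`
#' followed by a header (`predator,prey` for predation webs, `i,j`
#' otherwise) and one row per stored directed link, 1-based indices.
#' The round trip through [read_topology()] is exact.
#'
#' @param t an `lv_topology`.
#' @param path output file.
#' @export
write_topology <- function(t, path) {
  stopifnot(inherits(t, "lv_topology"))
  trophic <- t$model %in% c(STRUCTURED_MODELS, "unstructured_paired")
  header <- if (trophic) "predator,prey" else "i,j"
  idx <- which(t$alpha == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  lines <- c(
    sprintf("# S=%d model=%s C_target=%.10g", t$S, t$model, t$C_target),
    header,
    sprintf("%d,%d", idx[, 1], idx[, 2])
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a topology from an edge-list CSV
#'
#' Accepts the format written by [write_topology()]: an optional comment
#' line declaring `S` (otherwise the maximum index is used), a header, and
#' 1-based index pairs. Self-links and non-integer or out-of-range indices
#' are rejected with the offending line number.
#'
#' @param path input file.
#' @param S species count; overrides the header comment.
#' @return an `lv_topology`.
#' @export
read_topology <- function(path, S = NULL) {
  if (!file.exists(path)) stop_param("no such file: ", path)
  lines <- readLines(path)
  model <- "may_directed"
  C_target <- NA_real_
  offset <- 0
  if (length(lines) > 0 && startsWith(lines[1], "#")) {
    meta <- lines[1]
    get_field <- function(key) {
      m <- regmatches(meta, regexec(paste0(key, "=([^ ]+)"), meta))[[1]]
      if (length(m) == 2) m[2] else NA_character_
    }
    if (is.null(S) && !is.na(get_field("S"))) S <- as.integer(get_field("S"))
    if (!is.na(get_field("model"))) model <- get_field("model")
    if (!is.na(get_field("C_target"))) C_target <- as.numeric(get_field("C_target"))
    offset <- 1
  }
  if (length(lines) <= offset) stop_param("file ", path, " has no header line")
  offset <- offset + 1 # header row
  body <- lines[seq.int(offset + 1, length.out = max(0, length(lines) - offset))]
  body_lineno <- seq_along(body) + offset
  keep <- nzchar(trimws(body))
  body <- body[keep]; body_lineno <- body_lineno[keep]

  parse_row <- function(row, lineno) {
    parts <- strsplit(row, ",", fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(trimws(parts)))
    if (length(vals) != 2 || any(is.na(vals)) || any(vals != round(vals)))
      stop_param("line ", lineno, ": expected two integer indices, got '",
                 row, "'")
    if (vals[1] == vals[2])
      stop_param("line ", lineno, ": self-link '", row,
                 "' is not allowed (intraspecific effects live in theta)")
    as.integer(vals)
  }
  edges <- mapply(parse_row, body, body_lineno, SIMPLIFY = FALSE)
  edges <- do.call(rbind, c(edges, list(matrix(integer(0), 0, 2))))
  if (is.null(S)) {
    if (nrow(edges) == 0)
      stop_param("cannot infer S from an empty link file; pass `S` or add ",
                 "a '# S=' header comment")
    S <- max(edges)
  }
  bad <- which(edges < 1 | edges > S, arr.ind = TRUE)
  if (length(bad) > 0)
    stop_param("line ", body_lineno[bad[1, 1]], ": index outside 1..", S)
  alpha <- matrix(0L, S, S)
  if (nrow(edges) > 0) alpha[edges] <- 1L
  if (is.na(C_target)) C_target <- max(sum(alpha) / (S * (S - 1)), 1e-12)
  if (!model %in% TOPOLOGY_MODELS) model <- "may_directed"
  new_topology(S, alpha, model, C_target)
}

#' Write a machine-readable run manifest
#'
#' Records everything needed to reproduce a run with the same
#' implementation version: the configuration snapshot, the seed, the
#' package version, a timestamp, and an inventory of output files with MD5
#' checksums.
#'
#' @param path manifest file (JSON).
#' @param config an `lv_config`.
#' @param seed the base seed of the run (may be `NULL`).
#' @param outputs character vector of output file paths.
#' @return the manifest list, invisibly.
#' @export
write_run_manifest <- function(path, config, seed = NULL, outputs = character(0)) {
  stopifnot(inherits(config, "lv_config"))
  existing <- outputs[file.exists(outputs)]
  manifest <- list(
    tool = "lvfeas",
    version = as.character(utils::packageVersion("lvfeas")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = unclass_config(config),
    outputs = if (length(existing) > 0)
      data.frame(file = basename(existing),
                 md5 = unname(tools::md5sum(existing)))
    else list()
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}

# plain-list view of a config for serialization
unclass_config <- function(config) {
  out <- unclass(config)
  out$rates <- unclass(out$rates)
  out$n_reps <- attr(config, "n_reps")
  out
}
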