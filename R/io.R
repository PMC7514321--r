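# File formats. TPM JSON: {"n_nodes", "node_labels", "dialect",
# "state_ordering": "little_endian", "matrix": nested lists}. TPM CSV:
# header of next-state labels, one row per prior state keyed by its bit
# string. Deterministic systems round-trip bit-exactly (0/1 entries).

#' Read and write TPM files
#'
#' The format is chosen by file extension: `.json` stores either dialect
#' with its metadata; `.csv` stores the state-by-state matrix with prior
#' states as row keys and next states as column labels. Both use
#' little-endian state ordering and round-trip deterministic systems
#' bit-exactly.
#'
#' @param x A `tpm` object.
#' @param path File path ending in `.json` or `.csv`.
#' @param dialect For JSON output: which matrix to store. State-by-node is
#'   the default when available (more compact, implies the factorisation).
#' @param strict Passed to [tpm_from_matrix()] when reading a
#'   state-by-state matrix.
#' @return `read_tpm()` returns a `tpm`; `write_tpm()` returns `path`
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".json")
#' write_tpm(fixture_tpm("mcx"), f)
#' read_tpm(f)
#' @export
write_tpm <- function(x, path,
                      dialect = c("auto", "state_by_state", "state_by_node")) {
  stopifnot(inherits(x, "tpm"))
  dialect <- match.arg(dialect)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    m <- x$state_by_state
    utils::write.csv(as.data.frame(m), path, row.names = TRUE)
    return(invisible(path))
  }
  if (ext != "json") stop("unsupported TPM file extension: ", ext)
  if (dialect == "auto") {
    dialect <- if (!is.null(x$state_by_node)) "state_by_node" else "state_by_state"
  }
  if (dialect == "state_by_node" && is.null(x$state_by_node)) {
    stop("TPM has no state-by-node form")
  }
  m <- if (dialect == "state_by_node") x$state_by_node else x$state_by_state
  obj <- list(
    n_nodes = x$n_nodes,
    node_labels = x$node_labels,
    dialect = dialect,
    state_ordering = "little_endian",
    matrix = unname(apply(m, 1, as.numeric, simplify = FALSE))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tpm
#' @export
read_tpm <- function(path, strict = TRUE) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    return(tpm_from_matrix(as.matrix(df), "state_by_state", strict = strict))
  }
  if (ext != "json") stop("unsupported TPM file extension: ", ext)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$state_ordering, "little_endian")) {
    stop("unsupported state ordering: ", obj$state_ordering)
  }
  m <- obj$matrix
  if (is.list(m)) m <- do.call(rbind, m)
  tpm_from_matrix(m, obj$dialect, node_labels = obj$node_labels,
                  strict = strict)
}

#' Export a composition table
#'
#' Writes the per-subset phi values of a [composition()] either as a CSV in
#' the familiar summary layout (subsets as columns, one row each for phiC and
#' phiE, plus the sums) or as JSON including the minimum information
#' partitions.
#'
#' @param comp A `composition` object.
#' @param path Output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_composition <- function(comp, path) {
  stopifnot(inherits(comp, "composition"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    wide <- tidyr_pivot(comp$table)
    wide[["sum"]] <- c(comp$sum_phi_c, comp$sum_phi_e)
    utils::write.csv(cbind(phi = rownames(wide), wide), path,
                     row.names = FALSE)
    return(invisible(path))
  }
  if (ext != "json") stop("unsupported extension: ", ext)
  obj <- list(
    state = comp$state_label,
    node_labels = comp$node_labels,
    sum_phi_c = comp$sum_phi_c,
    sum_phi_e = comp$sum_phi_e,
    total = comp$total,
    subsets = lapply(seq_len(nrow(comp$table)), function(i) {
      row <- comp$table[i, ]
      list(
        subset = row$subset,
        state = row$subset_state,
        direction = row$direction,
        phi = row$phi,
        mip = row$mip,
        effective_purview = row$effective_purview
      )
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
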