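#' Read a compound table from CSV
#'
#' Reads a CSV of compounds (one row each) into a data frame with the
#' canonical columns `id`, `smiles` and `log_papp` plus any metadata columns
#' present in the file. `log_papp` is the base-10 logarithm of apparent
#' permeability in cm/s; blank, `NA` or `NaN` cells become `NA`.
#'
#' @param path Path to a CSV file (RFC-4180, UTF-8, '.' decimal separator)
#'   with a header row.
#' @param column_map Named character vector mapping the canonical names
#'   `id`, `smiles`, `log_papp` to the column names used in the file.
#'   `log_papp` may be omitted for structure-only tables.
#' @return A data frame with columns `id`, `smiles`, optionally `log_papp`,
#'   and any remaining file columns as metadata, in file row order.
#' @export
read_compound_table <- function(path,
                                column_map = c(id = "id", smiles = "smiles",
                                               log_papp = "log_papp")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = c("", "NA", "NaN"))
  need <- column_map[intersect(c("id", "smiles"), names(column_map))]
  miss <- setdiff(unname(need), names(df))
  if (length(miss)) {
    stop("compound table is missing mapped column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(id = as.character(df[[column_map[["id"]]]]),
                    smiles = as.character(df[[column_map[["smiles"]]]]),
                    stringsAsFactors = FALSE)
  if (any(!nzchar(out$id) | is.na(out$id))) {
    stop("empty compound id at row(s): ",
         paste(which(!nzchar(out$id) | is.na(out$id)), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(out$id)) {
    dup <- out$id[duplicated(out$id)][1L]
    rows <- which(out$id == dup)
    stop("duplicate compound id '", dup, "' at rows ",
         paste(rows, collapse = " and "), call. = FALSE)
  }
  if ("log_papp" %in% names(column_map) &&
      column_map[["log_papp"]] %in% names(df)) {
    raw <- df[[column_map[["log_papp"]]]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(val))
    if (length(bad)) {
      stop("unparseable log_papp value at row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    out$log_papp <- val
  }
  meta <- setdiff(names(df), unname(column_map))
  for (m in meta) out[[m]] <- df[[m]]
  out
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to canonical form through the OpenBabel backend so that
#' different writings of the same structure (e.g. `"OCC"` and `"CCO"`)
#' compare equal. Strings OpenBabel cannot parse yield `NA`.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, `NA` where parsing failed.
#' @export
canonicalize_smiles <- function(smiles) {
  if (!length(smiles)) return(character(0))
  convert_batch <- function(smi, tags) {
    src <- paste0(smi, " ", tags, collapse = "\n")
    out <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", source = paste0(src, "\n")),
      error = function(e) ""
    )
    lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
    res <- stats::setNames(rep(NA_character_, length(smi)), tags)
    for (ln in lines[nzchar(lines)]) {
      parts <- strsplit(ln, "[ \t]+")[[1]]
      if (length(parts) >= 2 && parts[2] %in% tags) res[parts[2]] <- parts[1]
    }
    res
  }
  tags <- paste0("m", seq_along(smiles))
  res <- convert_batch(smiles, tags)
  # a parse failure can abort the batch; retry the unresolved ones singly
  for (i in which(is.na(res))) {
    res[i] <- convert_batch(smiles[i], tags[i])
  }
  unname(res)
}

#' Remove duplicated compounds by canonical structure
#'
#' Compares structures after SMILES canonicalization and keeps the first
#' occurrence of each unique structure, preserving input order otherwise.
#' Records whose SMILES fail to parse are excluded and counted separately.
#'
#' @param records Data frame with at least `id` and `smiles` columns (as from
#'   [read_compound_table()]).
#' @return List with `kept` (data frame), `removed` (count of canonical
#'   duplicates dropped) and `failed` (data frame of unparseable records).
#' @export
deduplicate_compounds <- function(records) {
  stopifnot(is.data.frame(records), all(c("id", "smiles") %in% names(records)))
  can <- canonicalize_smiles(records$smiles)
  failed <- is.na(can)
  if (any(failed)) {
    warning(sum(failed), " structure(s) failed to parse and were excluded: ",
            paste(utils::head(records$id[failed], 5), collapse = ", "),
            call. = FALSE)
  }
  ok <- records[!failed, , drop = FALSE]
  can_ok <- can[!failed]
  dup <- duplicated(can_ok)
  list(kept = ok[!dup, , drop = FALSE],
       removed = sum(dup),
       failed = records[failed, , drop = FALSE])
}

#' Apparent permeability from a transport measurement
#'
#' Computes log10 Papp from the in vitro monolayer transport quantities:
#' Papp = (dQ/dt) / (C0 x A), with Papp in cm/s.
#'
#' @param dqdt Drug permeation rate across the monolayer, micromol/s.
#' @param c0 Initial donor-compartment concentration, micromol/cm^3
#'   (1 micromol/cm^3 = 1 mM).
#' @param area Monolayer area, cm^2.
#' @return log10(Papp), with Papp in cm/s. Vectorized over the inputs.
#' @export
compute_log_papp <- function(dqdt, c0, area) {
  if (any(!is.finite(dqdt)) || any(!is.finite(c0)) || any(!is.finite(area)) ||
      any(dqdt <= 0) || any(c0 <= 0) || any(area <= 0)) {
    stop("dqdt, c0 and area must all be finite and strictly positive",
         call. = FALSE)
  }
  log10(dqdt / (c0 * area))
}

#' Read / write a descriptor matrix as CSV
#'
#' The on-disk form has the compound id in the first column and one numeric
#' column per descriptor; empty cells (and `NA`/`NaN`) are missing values.
#' `write_descriptor_matrix()` writes at full double precision (15
#' significant digits) so a write/read round trip reproduces the matrix.
#'
#' @param path CSV file path.
#' @return `read_descriptor_matrix()` returns a descriptor matrix (see
#'   [as_descriptor_matrix()]); `write_descriptor_matrix()` returns `path`
#'   invisibly.
#' @export
read_descriptor_matrix <- function(path) {
  dt <- data.table::fread(path, sep = ",", header = TRUE,
                          na.strings = c("", "NA", "NaN"),
                          colClasses = list(character = 1), data.table = FALSE,
                          check.names = FALSE)
  if (anyDuplicated(names(dt))) {
    dup <- unique(names(dt)[duplicated(names(dt))])
    stop("duplicate descriptor column(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  ids <- as.character(dt[[1]])
  vals <- dt[, -1, drop = FALSE]
  nonnum <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(nonnum)) {
    stop("non-numeric descriptor column(s): ", paste(nonnum, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  as_descriptor_matrix(m)
}

#' @rdname read_descriptor_matrix
#' @param m Descriptor matrix.
#' @export
write_descriptor_matrix <- function(m, path) {
  m <- as_descriptor_matrix(m)
  dt <- data.table::data.table(id = rownames(m))
  for (j in colnames(m)) {
    # %.17g guarantees an exact double round trip
    dt[[j]] <- ifelse(is.na(m[, j]), "", sprintf("%.17g", m[, j]))
  }
  data.table::fwrite(dt, path, sep = ",", na = "", quote = FALSE)
  invisible(path)
}

#' Read a molecular-property table
#'
#' Reads the physicochemical-property CSV consumed by the drug-likeness rule
#' sets: one row per compound with an `id` column and numeric property
#' columns (`mw`, `mlogp`, `hba`, `hbd`, `rbn`, `tpsa`, `n_rings`,
#' `formal_charge`, `csp3_ratio`, `h_ratio`, `no_to_csp3`, `unsat_p`).
#'
#' @param path CSV file path.
#' @return Data frame with `id` as character and properties numeric.
#' @export
read_property_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = c("", "NA", "NaN"))
  if (!"id" %in% names(df)) stop("property table needs an 'id' column",
                                 call. = FALSE)
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) stop("duplicate ids in property table",
                                 call. = FALSE)
  df
}
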