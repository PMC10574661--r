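#' Standardize raw SMILES into curated molecule records
#'
#' Applies the library-curation rules used throughout the package: the input
#' is parsed and canonicalized, alkali/alkaline-earth counter-ions of simple
#' salts are disconnected and removed, only the largest organic fragment
#' (most heavy atoms; ties broken by longer canonical SMILES, then
#' lexicographically) is retained, and the result is reported as canonical
#' isomeric SMILES. Charged acids/bases are kept as-is; no neutralization,
#' tautomer canonicalization or protonation enumeration is attempted.
#'
#' @param smiles character vector of raw SMILES strings.
#' @return A data.frame with one row per input: `input`, `smiles` (canonical
#'   isomeric SMILES, `NA` on rejection), `ok` (logical) and `reason`
#'   (`""`, `"parse_error"` or `"inorganic"`).
#' @examples
#' \dontrun{
#' standardize_smiles(c("CC(=O)[O-].[Na+]", "c1ccccc1", "not_a_smiles"))
#' }
#' @export
standardize_smiles <- function(smiles) {
  smiles <- as.character(smiles)
  n <- length(smiles)
  out <- data.frame(input = smiles,
                    smiles = rep(NA_character_, n),
                    ok = rep(FALSE, n),
                    reason = rep("parse_error", n),
                    stringsAsFactors = FALSE)
  if (!n) return(out)
  can <- ob_canonical(smiles)
  parsed <- !is.na(can)
  # pick the retained fragment for every parsed molecule
  keep <- rep(NA_character_, length(smiles))
  reason <- ifelse(parsed, "", "parse_error")
  frag_lists <- strsplit(ifelse(parsed, can, ""), ".", fixed = TRUE)
  for (i in which(parsed)) {
    frags <- frag_lists[[i]]
    if (length(frags) > 1L) {
      # drop single-atom salt metals, then anything without carbon
      elem <- lapply(frags, smiles_elements)
      is_salt <- vapply(elem, function(e)
        length(e) == 1L && e %in% SALT_METALS, TRUE)
      frags <- frags[!is_salt]
      elem <- elem[!is_salt]
      organic <- vapply(elem, function(e) "C" %in% e, TRUE)
      frags <- frags[organic]
      elem <- elem[organic]
      if (!length(frags)) { reason[i] <- "inorganic"; next }
      nha <- vapply(elem, length, 0L)
      ord <- order(-nha, -nchar(frags), frags)
      keep[i] <- frags[ord[1L]]
    } else {
      if (!("C" %in% smiles_elements(frags))) { reason[i] <- "inorganic"; next }
      keep[i] <- frags
    }
  }
  # re-canonicalize retained fragments (fragment extraction can change the
  # canonical form)
  todo <- which(!is.na(keep))
  if (length(todo)) {
    recan <- ob_canonical(keep[todo])
    keep[todo] <- recan
    reason[todo][is.na(recan)] <- "parse_error"
  }
  out$smiles <- keep
  out$ok <- !is.na(keep)
  out$reason <- ifelse(out$ok, "", reason)
  out
}

#' Construct a table of molecule records
#'
#' A molecule record table is the package's standard container for a compound
#' library: a data.frame with columns `id`, `smiles` (canonical isomeric),
#' `source`, and optional activity columns `ic50_um` (half-maximal inhibitory
#' concentration, micromolar, positive) and `pic50`.
#'
#' @param smiles canonical SMILES (use [standardize_smiles()] on raw input).
#' @param id unique identifiers; generated when `NULL`.
#' @param source free source tag recycled across records.
#' @param ic50_um optional IC50 values in micromolar (must be positive).
#' @param pic50 optional pIC50 values; computed from `ic50_um` when missing.
#' @return data.frame of class `molecule_records`.
#' @export
molecule_records <- function(smiles, id = NULL, source = "unknown",
                             ic50_um = NULL, pic50 = NULL) {
  n <- length(smiles)
  if (is.null(id)) id <- sprintf("mol%05d", seq_len(n))
  stopifnot(length(id) == n, !anyDuplicated(id))
  if (!is.null(ic50_um)) {
    stopifnot(length(ic50_um) == n)
    if (any(!is.na(ic50_um) & ic50_um <= 0)) {
      stop("ic50_um must be positive")
    }
  }
  df <- data.frame(id = as.character(id), smiles = as.character(smiles),
                   source = rep_len(as.character(source), n),
                   stringsAsFactors = FALSE)
  df$ic50_um <- if (is.null(ic50_um)) rep(NA_real_, n) else
    as.numeric(ic50_um)
  df$pic50 <- if (is.null(pic50)) {
    ifelse(is.na(df$ic50_um), NA_real_, pic50_from_ic50(df$ic50_um))
  } else {
    as.numeric(pic50)
  }
  class(df) <- c("molecule_records", "data.frame")
  df
}

#' Remove duplicate molecules
#'
#' Exactly one record per distinct canonical isomeric SMILES is kept (the
#' first occurrence); input order is otherwise preserved. The duplicate key
#' is stereo-aware: E/Z and R/S isomers are distinct molecules.
#'
#' @param records a `molecule_records` data.frame.
#' @return the deduplicated records.
#' @export
deduplicate_records <- function(records) {
  stopifnot(is.data.frame(records), "smiles" %in% names(records))
  records[!duplicated(records$smiles), , drop = FALSE]
}

#' Read a compound library from CSV or SDF
#'
#' CSV input must have a header with a `smiles` column; `id`, `source`,
#' `ic50_um` and `pic50` columns are used when present. SDF input reads
#' molecule titles as ids and the `IC50_uM` data field as activity. Every
#' molecule is passed through [standardize_smiles()]; rows that fail are
#' skipped with a message, and the number of skips is attached as attribute
#' `n_skipped`.
#'
#' @param path file path.
#' @param format `"csv"` or `"sdf"`.
#' @param standardize standardize and drop failing rows (default `TRUE`).
#' @return a `molecule_records` data.frame.
#' @export
read_library <- function(path, format = c("csv", "sdf"), standardize = TRUE) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    if (!"smiles" %in% names(df)) stop("CSV is missing a 'smiles' column")
    raw <- df$smiles
    id <- if ("id" %in% names(df)) as.character(df$id) else
      sprintf("mol%05d", seq_len(nrow(df)))
    src <- if ("source" %in% names(df)) df$source else "csv"
    ic50 <- if ("ic50_um" %in% names(df)) as.numeric(df$ic50_um) else NULL
    pic <- if ("pic50" %in% names(df)) as.numeric(df$pic50) else NULL
  } else {
    sdf <- ChemmineR::read.SDFset(path)
    suppressWarnings(ChemmineR::cid(sdf) <-
      ChemmineR::makeUnique(ChemmineR::sdfid(sdf)))
    id <- ChemmineR::cid(sdf)
    raw <- unname(vapply(seq_along(id), function(i) {
      s <- ChemmineR::sdf2str(sdf[[i]])
      sdf_to_canonical(paste(s, collapse = "\n"))[1]
    }, ""))
    props <- lapply(seq_along(id),
                    function(i) ChemmineR::datablock(sdf[[i]]))
    getp <- function(p, key) if (key %in% names(p)) as.numeric(p[[key]]) else NA_real_
    ic50 <- vapply(props, getp, 0, key = "IC50_uM")
    pic <- vapply(props, getp, 0, key = "pIC50")
    if (all(is.na(ic50))) ic50 <- NULL
    if (!is.null(pic) && all(is.na(pic))) pic <- NULL
    src <- "sdf"
  }
  if (standardize) {
    std <- standardize_smiles(raw)
    drop <- !std$ok
    if (any(drop)) {
      message(sum(drop), " molecule(s) skipped during standardization (",
              paste(unique(std$reason[drop]), collapse = ", "), ")")
    }
    keep <- which(!drop)
    rec <- molecule_records(std$smiles[keep], id = id[keep],
                            source = if (length(src) == 1L) src else src[keep],
                            ic50_um = if (is.null(ic50)) NULL else ic50[keep],
                            pic50 = if (is.null(pic)) NULL else pic[keep])
    attr(rec, "n_skipped") <- sum(drop)
  } else {
    rec <- molecule_records(raw, id = id, source = src,
                            ic50_um = ic50, pic50 = pic)
    attr(rec, "n_skipped") <- 0L
  }
  rec
}

#' Write a compound library to CSV or SDF
#'
#' The CSV dialect is UTF-8, comma-separated, header row, columns
#' `id, smiles, source, ic50_um, pic50`. SDF output stores the id as the
#' molecule title and the activity as an `IC50_uM` data field, so a
#' write/read round trip preserves id, SMILES and activity.
#'
#' @param records a `molecule_records` data.frame.
#' @param path output file path.
#' @param format `"csv"` or `"sdf"`.
#' @return `path`, invisibly.
#' @export
write_library <- function(records, path, format = c("csv", "sdf")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(records)[
      , c("id", "smiles", "source", "ic50_um", "pic50")],
      path, row.names = FALSE)
  } else {
    sdf <- smiles_to_sdfset(records$smiles, records$id)
    db <- lapply(seq_len(nrow(records)), function(i) {
      v <- c(id = records$id[i], source = records$source[i])
      if (!is.na(records$ic50_um[i])) v <- c(v, IC50_uM = records$ic50_um[i])
      if (!is.na(records$pic50[i])) v <- c(v, pIC50 = records$pic50[i])
      v
    })
    names(db) <- records$id
    ChemmineR::datablock(sdf) <- db
    ChemmineR::write.SDF(sdf, path, cid = TRUE)
  }
  invisible(path)
}

#' @export
print.molecule_records <- function(x, ...) {
  cat("<molecule_records> ", nrow(x), " molecules",
      if (any(!is.na(x$ic50_um)) || any(!is.na(x$pic50)))
        " (with activity)" else "", "\n", sep = "")
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat("... ", nrow(x) - 6L, " more rows\n", sep = "")
  invisible(x)
}
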