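# Low-level OpenBabel plumbing shared by the io/featurize/chemspace modules.
# Batch operations go through the obabel CLI (one process per batch); SDF-set
# level work (properties, SMARTS counts, atom subsetting) goes through
# ChemmineR/ChemmineOB.

ob_available <- function() nzchar(Sys.which("obabel"))

# Run obabel on a set of SMILES, one line per molecule, titles = index tokens
# so results can be mapped back even when some molecules fail to parse.
ob_smiles_run <- function(smiles, out_args) {
  stopifnot(is.character(smiles))
  if (!ob_available()) stop("obabel executable not found on PATH")
  fin <- tempfile(fileext = ".smi")
  fout <- tempfile()
  on.exit(unlink(c(fin, fout)), add = TRUE)
  ok <- !is.na(smiles) & nzchar(smiles) & !grepl("[[:space:]]", smiles)
  idx <- which(ok)
  if (length(idx) == 0L) return(list(lines = character(0), idx = integer(0)))
  writeLines(paste(smiles[idx], paste0("t", idx)), fin)
  system2("obabel", c(fin, out_args, "-e", "-O", fout),
          stdout = FALSE, stderr = FALSE)
  lines <- if (file.exists(fout)) readLines(fout, warn = FALSE) else character(0)
  list(lines = lines, idx = idx)
}

# Canonical (isomeric) SMILES; NA where OpenBabel cannot parse the input.
ob_canonical <- function(smiles) {
  out <- rep(NA_character_, length(smiles))
  res <- ob_smiles_run(smiles, c("-ocan"))
  if (length(res$lines) == 0L) return(out)
  parts <- strsplit(res$lines, "\t", fixed = TRUE)
  smi <- vapply(parts, `[`, "", 1L)
  ttl <- trimws(vapply(parts, function(p) if (length(p) > 1L) p[2L] else "", ""))
  hit <- grepl("^t[0-9]+$", ttl) & nzchar(smi)
  pos <- as.integer(sub("^t", "", ttl[hit]))
  out[pos] <- smi[hit]
  out
}

# Fingerprints in FPS format. Returns a 0/1 integer matrix with one row per
# input molecule (NA rows for unparsable molecules are not allowed: callers
# pass standardized SMILES and an error is raised on any failure).
ob_fps <- function(smiles, fp = c("MACCS", "ECFP4", "FP2")) {
  fp <- match.arg(fp)
  res <- ob_smiles_run(smiles, c("-ofps", "-xf", fp))
  lines <- res$lines[!startsWith(res$lines, "#")]
  if (length(lines) != length(smiles)) {
    stop("fingerprint computation failed for ",
         length(smiles) - length(lines), " molecule(s); ",
         "standardize the library first")
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  hex <- vapply(parts, `[`, "", 1L)
  ttl <- trimws(vapply(parts, `[`, "", 2L))
  pos <- as.integer(sub("^t", "", ttl))
  bits <- hex_to_bits(hex)
  mat <- matrix(0L, length(smiles), ncol(bits))
  mat[pos, ] <- bits
  mat
}

# Decode FPS hex strings into a bit matrix (rows = strings). FPS layout:
# bytes in fingerprint order, LSB-first within each byte (verified
# bit-for-bit against ChemmineOB::fingerprint_OB in the test suite).
hex_to_bits <- function(hex) {
  lut <- t(vapply(0:255, function(b) bitwAnd(bitwShiftR(b, 0:7), 1L),
                  integer(8)))
  n <- length(hex)
  nc <- nchar(hex[1L])
  out <- matrix(0L, n, nc * 4L)
  from <- seq(1L, nc, 2L)
  for (k in seq_len(n)) {
    bytes <- strtoi(substring(hex[k], from, from + 1L), 16L)
    out[k, ] <- as.integer(t(lut[bytes + 1L, , drop = FALSE]))
  }
  out
}

# Convert standardized SMILES to a ChemmineR SDFset (batched, one obabel
# call). Row order follows the input; ids become the compound ids.
smiles_to_sdfset <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- paste0("cmp", seq_along(smiles))
  res <- ob_smiles_run(smiles, c("-osdf"))
  if (length(res$lines) == 0L) stop("no molecule could be converted to SDF")
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(res$lines, tf)
  sdf <- ChemmineR::read.SDFset(tf)
  got <- as.integer(sub("^t", "", ChemmineR::sdfid(sdf)))
  if (length(got) != length(smiles)) {
    stop("SDF conversion failed for ", length(smiles) - length(got),
         " molecule(s)")
  }
  sdf <- sdf[order(got)]
  suppressWarnings(ChemmineR::cid(sdf) <- ids)
  sdf
}

# Canonical SMILES for each molecule of an SDF string (batched). Returns a
# vector named by the molecule titles, so callers can map results back even
# if a molecule is skipped.
sdf_to_canonical <- function(sdf_strings) {
  if (!length(sdf_strings)) return(character(0))
  fin <- tempfile(fileext = ".sdf")
  fout <- tempfile()
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(sdf_strings, fin)
  system2("obabel", c(fin, "-ocan", "-e", "-O", fout),
          stdout = FALSE, stderr = FALSE)
  lines <- if (file.exists(fout)) readLines(fout, warn = FALSE) else character(0)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- vapply(parts, `[`, "", 1L)
  names(out) <- trimws(vapply(parts, function(p)
    if (length(p) > 1L) p[2L] else "", ""))
  out
}

# Heavy-atom element symbols of a single SMILES string, by direct
# tokenization (bracket atoms plus the organic subset). Hydrogens, bond
# symbols, ring closures and branches are skipped. Used only for salt/
# fragment bookkeeping where a full parse is unnecessary.
smiles_elements <- function(smiles) {
  if (is.na(smiles) || !nzchar(smiles)) return(character(0))
  elems <- character(0)
  brackets <- regmatches(smiles, gregexpr("\\[[^]]*\\]", smiles))[[1]]
  for (b in brackets) {
    m <- regmatches(b, regexec("^\\[[0-9]*([A-Z][a-z]?|[a-z]{1,2})", b))[[1]]
    if (length(m) == 2L && m[2] != "H") elems <- c(elems, sym_case(m[2]))
  }
  rest <- gsub("\\[[^]]*\\]", "", smiles)
  toks <- regmatches(rest, gregexpr("Cl|Br|[BCNOPSFI]|[bcnops]", rest))[[1]]
  c(elems, vapply(toks, sym_case, "", USE.NAMES = FALSE))
}

sym_case <- function(s) {
  paste0(toupper(substr(s, 1L, 1L)),
         if (nchar(s) > 1L) substr(s, 2L, nchar(s)) else "")
}

heavy_atom_count <- function(smiles) {
  vapply(smiles, function(s) length(smiles_elements(s)), 0L, USE.NAMES = FALSE)
}

# Alkali and alkaline-earth metals treated as salt counter-ions when they
# appear as single-atom fragments of a multi-fragment SMILES.
SALT_METALS <- c("Li", "Na", "K", "Rb", "Cs", "Fr",
                 "Be", "Mg", "Ca", "Sr", "Ba", "Ra")
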