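# Molecule input: SMILES / SDF parsing, canonicalization and identity keys.

#' Canonicalize a SMILES string
#'
#' Canonical isomeric SMILES via Open Babel. Invalid structures give
#' \code{NA}.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical SMILES (\code{NA} where invalid).
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN",
                                                 paste0(s, "\tm\n"))),
      error = function(e) ""
    )
    out <- sub("[\t ].*$", "", trimws(out))
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

# heavy-atom count of a SMILES fragment, by atom-token counting
.heavy_atom_count <- function(smiles) {
  toks <- gregexpr(
    "\\[[^\\]]*\\]|Cl|Br|Si|Se|B|C|N|O|P|S|F|I|b|c|n|o|p|s",
    smiles
  )[[1]]
  if (toks[1L] == -1L) return(0L)
  # bracket atoms that are explicit hydrogens do not count as heavy
  m <- regmatches(smiles, gregexpr(
    "\\[[^\\]]*\\]|Cl|Br|Si|Se|B|C|N|O|P|S|F|I|b|c|n|o|p|s", smiles))[[1]]
  sum(!grepl("^\\[[0-9]*H[0-9+-]*\\]$", m))
}

#' Canonical identity key of a molecule
#'
#' Canonical isomeric SMILES of the largest fragment (salts and counterions
#' stripped), the conventional key for deduplicating ligands across datasets.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of keys (\code{NA} where the SMILES is invalid).
#' @examples
#' canonical_key(c("CCO", "OCC"))       # identical keys
#' canonical_key("CC(=O)O.[Na]")        # acetate fragment only
#' @export
canonical_key <- function(smiles) {
  can <- canonical_smiles(smiles)
  vapply(can, function(s) {
    if (is.na(s)) return(NA_character_)
    frags <- strsplit(s, ".", fixed = TRUE)[[1]]
    if (length(frags) == 1L) return(s)
    largest <- frags[which.max(vapply(frags, .heavy_atom_count, integer(1)))]
    # re-canonicalize the bare fragment so keys match single-fragment inputs
    out <- canonical_smiles(largest)
    if (is.na(out)) largest else out
  }, character(1), USE.NAMES = FALSE)
}

#' Parse molecules from a SMILES or SDF file
#'
#' SMILES files hold one molecule per line as \code{"SMILES<whitespace>id"};
#' SDF files are standard V2000/V3000 read through ChemmineR. Each parsed
#' molecule gets a canonical identity key (largest-fragment canonical
#' SMILES). In non-strict mode unparseable entries are skipped and counted;
#' in strict mode the first invalid entry is an error.
#'
#' @param source Path to the input file, or a character vector of lines for
#'   \code{format = "smiles"}.
#' @param format \code{"smiles"} or \code{"sdf"}.
#' @param strict Error on the first invalid entry instead of skipping it.
#' @return A data frame with columns \code{id}, \code{smiles},
#'   \code{canonical_key}, carrying a \code{parse_report} attribute
#'   (list with \code{n_parsed}, \code{n_skipped}, \code{skipped}).
#' @export
parse_molecules <- function(source, format = c("smiles", "sdf"),
                            strict = FALSE) {
  format <- match.arg(format)
  if (format == "smiles") {
    lines <- if (length(source) == 1L && file.exists(source)) {
      readLines(source, warn = FALSE)
    } else {
      as.character(source)
    }
    lines <- lines[nzchar(trimws(lines))]
    ids <- character(0); smis <- character(0); skipped <- character(0)
    for (li in seq_along(lines)) {
      parts <- strsplit(trimws(lines[li]), "[ \t]+")[[1]]
      smi <- parts[1L]
      id <- if (length(parts) >= 2L) parts[2L] else sprintf("mol%d", li)
      key <- canonical_key(smi)
      if (is.na(key)) {
        if (strict) stop(sprintf("invalid SMILES at line %d: '%s'", li, smi))
        skipped <- c(skipped, sprintf("line %d (%s)", li, id))
        next
      }
      ids <- c(ids, id); smis <- c(smis, smi)
    }
    keys <- if (length(smis)) canonical_key(smis) else character(0)
  } else {
    stopifnot(file.exists(source))
    blocks <- as(ChemmineR::read.SDFstr(source), "list")
    ids <- character(0); smis <- character(0); skipped <- character(0)
    keys <- character(0)
    for (bi in seq_along(blocks)) {
      block <- blocks[[bi]]
      name <- trimws(block[1L])
      if (!nzchar(name)) name <- sprintf("mol%d", bi)
      smi <- tryCatch({
        out <- suppressWarnings(ChemmineOB::convertFormat(
          "SDF", "CAN", paste(c(block, ""), collapse = "\n")))
        out <- sub("[\t ].*$", "", trimws(out))
        if (!nzchar(out)) stop("conversion failed")
        out
      }, error = function(e) NA_character_)
      key <- if (is.na(smi)) NA_character_ else canonical_key(smi)
      if (is.na(key)) {
        if (strict) stop(sprintf("invalid SDF record %d ('%s')", bi, name))
        skipped <- c(skipped, sprintf("record %d (%s)", bi, name))
        next
      }
      ids <- c(ids, name); smis <- c(smis, smi); keys <- c(keys, key)
    }
  }
  if (anyDuplicated(ids)) {
    stop("duplicate molecule ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  mols <- data.frame(id = ids, smiles = smis, canonical_key = keys,
                     stringsAsFactors = FALSE)
  attr(mols, "parse_report") <- list(
    n_parsed = nrow(mols), n_skipped = length(skipped), skipped = skipped
  )
  mols
}
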