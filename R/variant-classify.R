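#' Classify an ALT allele
#'
#' Follows 1000 Genomes nomenclature: insertions and deletions smaller than
#' 50 bp are INDELs; anything at or above 50 bp, any symbolic allele
#' (`<DEL>`, `<INS:ME:ALU>`, breakends), and anything annotated
#' `SVTYPE=...` or `VT=SV` is a structural variant. When a VT/SVTYPE
#' annotation is present it wins over the length rule; the 50 bp cutoff
#' applies only to unannotated alleles.
#'
#' @param ref REF allele string.
#' @param alt one ALT allele string (may be symbolic).
#' @param info named character vector of INFO key-value pairs (may carry
#'   `VT`, `SVTYPE`).
#' @return one of `"REF_IDENTICAL"`, `"SNV"`, `"MNP_SUBSTITUTION"`,
#'   `"INSERTION"`, `"DELETION"`, `"SV"`.
#' @examples
#' classify_allele("A", "T")                          # "SNV"
#' classify_allele("AT", "A")                         # "DELETION"
#' classify_allele("A", "<INS:ME:ALU>")               # "SV"
#' @export
classify_allele <- function(ref, alt, info = character(0)) {
  if (!nzchar(ref) || !nzchar(alt))
    stop_input("REF and ALT alleles must be non-empty")
  if (grepl("^<.*>$", alt) || grepl("[][]", alt)) return("SV")
  if ("SVTYPE" %in% names(info)) return("SV")
  vt <- if ("VT" %in% names(info)) info[["VT"]] else NA_character_
  if (!is.na(vt) && "SV" %in% strsplit(vt, ",", fixed = TRUE)[[1]])
    return("SV")
  if (grepl("[^ACGTN]", ref) || grepl("[^ACGTN]", alt))
    stop_input("non-ACGTN characters in allele REF='%s' ALT='%s'", ref, alt)
  if (alt == ref) return("REF_IDENTICAL")
  diff <- nchar(alt) - nchar(ref)
  annotated <- !is.na(vt) || "SVTYPE" %in% names(info)
  if (!annotated && abs(diff) >= 50L) return("SV")
  if (diff == 0L) return(if (nchar(ref) == 1L) "SNV" else "MNP_SUBSTITUTION")
  if (diff > 0L) "INSERTION" else "DELETION"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Vectorized record-level classification.
classify_record <- function(rec) {
  vapply(rec$alts, classify_allele, character(1),
         ref = rec$ref, info = rec$info, USE.NAMES = FALSE)
}
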