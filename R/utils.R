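# Internal helpers shared across modules.

# Classed conditions so callers (and the CLI) can map failures to exit codes.
stop_input <- function(fmt, ..., class = character()) {
  stop(structure(
    class = c(class, "haplalign_input_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

stop_overlap_insertion <- function(fmt, ...) {
  stop(structure(
    class = c("overlapping_insertion_error", "haplalign_error",
              "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

stop_engine_not_found <- function(engine) {
  stop(structure(
    class = c("engine_not_found", "haplalign_error", "error", "condition"),
    list(message = sprintf(
      "tree engine '%s' not found on PATH; use engine = \"nj\" or install it",
      engine), call = sys.call(-1))
  ))
}

#' Parse a region string
#'
#' Regions use the tabix convention `chrom:start-end`, 1-based inclusive on
#' both ends. Commas in coordinates are tolerated.
#'
#' @param region a string such as `"chr1:1001-2000"`.
#' @return a list with elements `chrom`, `start`, `end` (integers).
#' @examples
#' parse_region("chr1:1,001-2,000")
#' @export
parse_region <- function(region) {
  if (!is.character(region) || length(region) != 1L)
    stop_input("region must be a single string 'chrom:start-end'")
  m <- regmatches(region, regexec("^(.+):([0-9,]+)-([0-9,]+)$", region))[[1]]
  if (length(m) != 4L)
    stop_input("cannot parse region '%s'; expected 'chrom:start-end'", region)
  start <- as.integer(gsub(",", "", m[3]))
  end <- as.integer(gsub(",", "", m[4]))
  if (is.na(start) || is.na(end) || start < 1L || start > end)
    stop_input("invalid region '%s': need 1 <= start <= end", region)
  list(chrom = m[2], start = start, end = end)
}

# "chr1:100-200" -> "chr1_100-200", a filesystem-safe tag for output names.
region_tag <- function(region) gsub(":", "_", region, fixed = TRUE)

# Uniquify labels: first occurrence unchanged, k-th duplicate gets ".k".
uniquify_labels <- function(labels) {
  counts <- new.env(parent = emptyenv())
  vapply(labels, function(lb) {
    n <- if (is.null(counts[[lb]])) 0L else counts[[lb]]
    counts[[lb]] <- n + 1L
    if (n == 0L) lb else paste0(lb, ".", n + 1L)
  }, character(1), USE.NAMES = FALSE)
}

# Sanitize a nucleotide string: uppercase, map ambiguity codes other than N
# to N (with a warning), reject gaps.
sanitize_bases <- function(seq, what = "sequence") {
  seq <- toupper(seq)
  if (grepl("-", seq, fixed = TRUE))
    stop_input("%s contains gap characters", what)
  if (grepl("[^ACGTN]", seq)) {
    warning(sprintf("%s: ambiguity codes other than N mapped to N", what),
            call. = FALSE)
    seq <- gsub("[^ACGTN]", "N", seq)
  }
  seq
}

split_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
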