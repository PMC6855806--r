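# Low-level sequence helpers shared across modules. All heavy string ops go
# through Biostrings; these wrappers keep plain-character interfaces for the
# small fragments the designers shuffle around.

#' Reverse-complement of plain character DNA
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector, reverse complement of each element.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# complement without reversal (used for bottom-strand bookkeeping)
dna_complement <- function(x) {
  as.character(Biostrings::complement(Biostrings::DNAStringSet(x)))
}

#' GC fraction of a DNA string
#' @param x single DNA string.
#' @return numeric in \[0, 1\].
#' @export
gc_fraction <- function(x) {
  stopifnot(length(x) == 1L)
  n <- nchar(x)
  if (n == 0L) return(NA_real_)
  gc <- sum(strsplit(toupper(x), "")[[1]] %in% c("G", "C"))
  gc / n
}

# longest mononucleotide run
max_homopolymer_run <- function(x) {
  r <- rle(strsplit(toupper(x), "")[[1]])
  if (length(r$lengths) == 0L) return(0L)
  max(r$lengths)
}

# all start positions (1-based) of exact matches of `pattern` in `subject`,
# overlapping matches included
find_exact <- function(pattern, subject) {
  if (nchar(pattern) == 0L || nchar(pattern) > nchar(subject)) return(integer(0))
  as.integer(IRanges::start(
    Biostrings::matchPattern(pattern, Biostrings::DNAString(subject))))
}

# does `motif` occur in `subject` on either strand?
motif_on_either_strand <- function(motif, subject) {
  length(find_exact(motif, subject)) > 0L ||
    length(find_exact(revcomp(motif), subject)) > 0L
}

# run `code` under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# random DNA with a target GC fraction
random_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# random in-frame coding DNA free of stop codons (n must be divisible by 3)
random_codons <- function(n_nt) {
  stopifnot(n_nt %% 3 == 0)
  if (n_nt == 0L) return("")
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste(sample(sense, n_nt / 3, replace = TRUE), collapse = "")
}

# classed error constructor so the pipeline can catch per-gene failures
dropin_error <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "dropin_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
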