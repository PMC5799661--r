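# Genetic-code tables shared across modules. Codons are uppercase DNA triplets;
# the standard code from Biostrings is the single source of truth.

.genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

.codon_env <- new.env(parent = emptyenv())

# aa: named chr vector codon -> amino acid ("*" = stop)
codon_table <- function() {
  if (is.null(.codon_env$tab)) {
    aa <- .genetic_code()
    sense <- names(aa)[aa != "*"]
    fam <- split(sense, aa[sense])          # amino acid -> codons
    deg <- lengths(fam)                      # degeneracy per amino acid
    .codon_env$tab <- list(
      aa = aa,
      codons = names(aa),
      stop_codons = names(aa)[aa == "*"],
      sense_codons = sense,
      families = fam,
      degeneracy = deg,
      # synonymously degenerate families: everything but Met and Trp
      degenerate_families = fam[deg >= 2L]
    )
  }
  .codon_env$tab
}

split_codons <- function(cds) {
  cds <- toupper(as.character(cds))
  if (nchar(cds) %% 3L != 0L) {
    abort(sprintf("CDS length (%d) is not divisible by 3", nchar(cds)))
  }
  if (nchar(cds) == 0L) return(character(0))
  substring(cds, seq(1L, nchar(cds), by = 3L), seq(3L, nchar(cds), by = 3L))
}

translate_cds <- function(cds) {
  tab <- codon_table()
  paste(tab$aa[split_codons(cds)], collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Round half up to `digits` decimals (matches how published tables round,
# unlike base round()'s round-half-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # small epsilon absorbs binary representation error at exact half-values
  sign(x) * floor(abs(x) * p + 0.5 + 1e-7) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer")
  }
  as.integer(seed)
}

# All generator randomness flows through a local RNG so callers' global
# RNG state is untouched and identical seeds give byte-identical output.
with_local_seed <- function(seed, code) {
  seed <- assert_seed(seed)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}
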