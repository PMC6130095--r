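BASES <- c("A", "C", "G", "T")
SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

# Canonical 96-type table (COSMIC ordering): substitution groups C>A, C>G, C>T,
# T>A, T>C, T>G; within a group the 5' base varies first, then the 3' base,
# both alphabetical. Built once at load.
.type96_table <- local({
  g <- expand.grid(three_prime = BASES, five_prime = BASES,
                   substitution = SUBSTITUTIONS,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("substitution", "five_prime", "three_prime")]
  g$ref <- substr(g$substitution, 1L, 1L)
  g$alt <- substr(g$substitution, 3L, 3L)
  g$context <- paste0(g$five_prime, g$ref, g$three_prime)
  g$label <- paste0(g$five_prime, "[", g$substitution, "]", g$three_prime)
  g$index <- seq_len(96L)
  g
})

#' Canonical mutation-type tables
#'
#' The 96 pyrimidine-centric contextual substitution types and the 192
#' strand-resolved types (leading block first, then lagging), in the fixed
#' canonical order used by every catalog and signature in this package.
#'
#' @return `mutation_types_96()`: a data frame with one row per type
#'   (substitution, flanking bases, pyrimidine-centric trinucleotide context,
#'   label such as `"A[C>A]A"`, canonical index 1-96).
#'   `mutation_types_192()`: one row per strand-resolved type with the
#'   template (`leading`/`lagging`) and index 1-192.
#' @export
mutation_types_96 <- function() .type96_table

#' @rdname mutation_types_96
#' @export
mutation_types_192 <- function() {
  t96 <- .type96_table
  out <- rbind(t96, t96)
  out$template <- rep(c("leading", "lagging"), each = 96L)
  out$index <- seq_len(192L)
  out$label <- paste0(out$label, "_", out$template)
  out
}

# 32 pyrimidine-centric trinucleotides, in canonical (unique, sorted by
# central base then flanks as they appear in the 96-order) form.
pyrimidine_trinucs <- function() unique(.type96_table$context)

complement_bases <- function(x) chartr("ACGTN", "TGCAN", x)

# Vectorized reverse complement for fixed-width 3-mers.
revcomp3 <- function(x) {
  paste0(complement_bases(substr(x, 3L, 3L)),
         complement_bases(substr(x, 2L, 2L)),
         complement_bases(substr(x, 1L, 1L)))
}

# Map any plus-strand trinucleotide to its pyrimidine-centric representative
# plus the strand the central pyrimidine sits on.
pyr_trinuc <- function(trinuc) {
  central <- substr(trinuc, 2L, 2L)
  is_pyr <- central %in% c("C", "T")
  out <- ifelse(is_pyr, trinuc, revcomp3(trinuc))
  list(trinuc = out, pyr_strand = ifelse(is_pyr, "plus", "minus"))
}

# index into the 96-table from substitution + pyrimidine-centric context
type96_index <- function(substitution, context) {
  key <- paste(substitution, context)
  match(key, paste(.type96_table$substitution, .type96_table$context))
}

#' Classify somatic SNVs into the 96 contextual substitution types
#'
#' Each single-nucleotide variant is annotated by the pyrimidine of the
#' mutated Watson-Crick base pair: records whose reference base is a purine
#' are reverse-complemented (substitution and context as a unit) and flagged
#' as having their pyrimidine on the minus strand.
#'
#' @param mutations data frame with columns `sample`, `chrom`, `pos`
#'   (1-based), `ref`, `alt` and optionally `context` (plus-strand 3-mer
#'   centred on `pos`).
#' @param genome optional named `DNAStringSet`; used to look up contexts when
#'   the `context` column is absent, and to validate it when present.
#' @return list with `classified` (input rows plus `type96`, `pyr_strand`)
#'   and `rejected` (input rows plus a `reason` code: `ref_equals_alt`,
#'   `non_acgt`, `context_mismatch`, `unknown_chrom`, `out_of_range`).
#' @export
classify_mutations <- function(mutations, genome = NULL) {
  stopifnot(all(c("sample", "chrom", "pos", "ref", "alt") %in% names(mutations)))
  n <- nrow(mutations)
  reason <- rep(NA_character_, n)

  ref <- toupper(mutations$ref)
  alt <- toupper(mutations$alt)
  bad_base <- !(ref %in% BASES) | !(alt %in% BASES) |
    nchar(mutations$ref) != 1L | nchar(mutations$alt) != 1L
  reason[bad_base] <- "non_acgt"
  same <- !bad_base & ref == alt
  reason[same] <- "ref_equals_alt"

  ctx <- if ("context" %in% names(mutations)) toupper(mutations$context) else rep(NA_character_, n)

  if (!is.null(genome)) {
    known <- mutations$chrom %in% names(genome)
    reason[is.na(reason) & !known] <- "unknown_chrom"
    need <- is.na(reason)
    if (any(need)) {
      lens <- width(genome)[match(mutations$chrom, names(genome))]
      in_range <- need & mutations$pos >= 2L & mutations$pos <= lens - 1L
      reason[need & !in_range] <- "out_of_range"
      idx <- which(in_range)
      if (length(idx)) {
        looked <- as.character(Biostrings::subseq(
          genome[mutations$chrom[idx]],
          start = mutations$pos[idx] - 1L, width = 3L))
        mismatch <- !is.na(ctx[idx]) & ctx[idx] != looked
        reason[idx[mismatch]] <- "context_mismatch"
        ctx[idx] <- ifelse(is.na(ctx[idx]), looked, ctx[idx])
        ctx[idx[mismatch]] <- NA_character_
      }
    }
  }

  ok <- is.na(reason)
  bad_ctx <- ok & (is.na(ctx) | nchar(ctx) != 3L | substr(ctx, 2L, 2L) != ref |
                     !grepl("^[ACGT]{3}$", ctx))
  reason[bad_ctx] <- "context_mismatch"
  ok <- is.na(reason)

  ref_o <- ref
  alt_o <- alt
  ctx_o <- ctx
  minus <- ok & ref %in% c("A", "G")
  ref_o[minus] <- complement_bases(ref[minus])
  alt_o[minus] <- complement_bases(alt[minus])
  ctx_o[minus] <- revcomp3(ctx[minus])

  type96 <- rep(NA_integer_, n)
  type96[ok] <- type96_index(paste0(ref_o[ok], ">", alt_o[ok]), ctx_o[ok])
  reason[ok & is.na(type96)] <- "context_mismatch"
  ok <- is.na(reason)

  classified <- mutations[ok, , drop = FALSE]
  classified$context <- ctx[ok]
  classified$type96 <- type96[ok]
  classified$pyr_strand <- ifelse(minus[ok], "minus", "plus")
  rejected <- mutations[!ok, , drop = FALSE]
  rejected$reason <- reason[!ok]
  list(classified = classified, rejected = rejected)
}

#' Assign the replication template strand of a mutation
#'
#' In left-replicating regions the reference (plus/Watson) strand is the
#' template of the leading strand, so a pyrimidine on the plus strand is a
#' leading-template mutation; in right-replicating regions the assignment is
#' reversed.
#'
#' @param pyr_strand `"plus"` or `"minus"` (strand carrying the pyrimidine).
#' @param direction `"left"` or `"right"` (replication direction of the
#'   domain containing the mutation).
#' @return character vector, `"leading"` or `"lagging"`.
#' @export
assign_template <- function(pyr_strand, direction) {
  stopifnot(all(pyr_strand %in% c("plus", "minus")),
            all(direction %in% c("left", "right")))
  ifelse((pyr_strand == "plus") == (direction == "left"), "leading", "lagging")
}
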