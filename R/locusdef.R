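#' Window-based locus definition for one trait
#'
#' Iteratively takes the most significant unassigned SNP as a sentinel and
#' assigns every significant SNP within `half_window` bp on the same
#' chromosome to its locus, until no significant SNP remains. Ties in
#' p-value are broken by (CHR, POS, SNP) order so the procedure is
#' deterministic.
#'
#' @param stats `summary_stats`/`meta_result` for one trait, sorted or not.
#' @param threshold significance threshold on P.
#' @param half_window half-width of the locus window in bp (default 250 kb,
#'   i.e. a 500 kb window per sentinel).
#' @return data.frame of loci: chr, start, end (1-based closed span of
#'   member SNPs), sentinel, trait, p (sentinel p), n_snps, members
#'   (semicolon-joined SNP ids). Empty when nothing is significant.
#' @export
define_trait_loci <- function(stats, threshold, half_window = 250000) {
  trait <- attr(stats, "trait_id") %||% "trait"
  sig <- stats[!is.na(stats$P) & stats$P <= threshold, , drop = FALSE]
  out <- NULL
  while (nrow(sig)) {
    o <- order(sig$P, sig$CHR, sig$POS, sig$SNP)
    s <- sig[o[1], ]
    in_win <- sig$CHR == s$CHR & abs(sig$POS - s$POS) <= half_window
    mem <- sig[in_win, , drop = FALSE]
    out <- rbind(out, data.frame(
      chr = s$CHR, start = min(mem$POS), end = max(mem$POS),
      sentinel = s$SNP, sentinel_pos = s$POS, trait = trait, p = s$P,
      n_snps = nrow(mem), members = paste(mem$SNP, collapse = ";"),
      stringsAsFactors = FALSE))
    sig <- sig[!in_win, , drop = FALSE]
  }
  out %||% data.frame(chr = character(), start = integer(), end = integer(),
                      sentinel = character(), sentinel_pos = integer(),
                      trait = character(), p = numeric(), n_snps = integer(),
                      members = character())
}

#' Merge per-trait sentinel loci into a unique cross-trait locus list
#'
#' Transitively groups sentinel-trait pairs whose sentinel positions lie
#' within `half_window` bp of each other on the same chromosome (so a chain
#' of sentinels merges into one locus even when its ends are far apart), and
#' represents each merged locus by its lowest-p sentinel-trait pair. This
#' deterministically automates the visual disambiguation of overlapping
#' regional association patterns. Merging is independent of input order.
#'
#' @param trait_loci row-bound output of [define_trait_loci()] over all
#'   traits.
#' @param half_window merge radius around each sentinel in bp (default
#'   500 kb, i.e. a 1000 kb window).
#' @return data.frame of unique loci: chr, start, end (span of merged
#'   windows' sentinels' member SNPs), sentinel, lead trait, lead p,
#'   n_traits_assoc, traits (all merged trait ids), n_sentinels.
#' @export
merge_loci_across_traits <- function(trait_loci, half_window = 500000) {
  n <- nrow(trait_loci)
  if (!n) return(data.frame(chr = character(), start = integer(),
                            end = integer(), sentinel = character(),
                            lead_trait = character(), lead_p = numeric(),
                            n_traits_assoc = integer(), traits = character(),
                            n_sentinels = integer()))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (trait_loci$chr[i] == trait_loci$chr[j] &&
        abs(trait_loci$sentinel_pos[i] - trait_loci$sentinel_pos[j]) <= half_window) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  grp <- vapply(seq_len(n), find, 0L)
  out <- lapply(unique(grp), function(g) {
    m <- trait_loci[grp == g, , drop = FALSE]
    o <- order(m$p, m$chr, m$sentinel_pos, m$sentinel)
    lead <- m[o[1], ]
    data.frame(chr = lead$chr, start = min(m$start), end = max(m$end),
               sentinel = lead$sentinel, sentinel_pos = lead$sentinel_pos,
               lead_trait = lead$trait, lead_p = lead$p,
               n_traits_assoc = length(unique(m$trait)),
               traits = paste(sort(unique(m$trait)), collapse = ";"),
               n_sentinels = nrow(m), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$chr, out$start), , drop = FALSE]
}
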