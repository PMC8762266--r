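#' Per-site allele frequencies in a population subset
#'
#' @param haps A [haplotype_set()].
#' @param pop Population label to restrict to, or `"ALL"` (default) for
#'   every haplotype.
#' @return Data frame with columns `site` (column index), `position_bp`,
#'   `freq` (allele-1 frequency) and `maf`.
#' @export
site_frequencies <- function(haps, pop = "ALL") {
  stopifnot(inherits(haps, "haplotype_set"))
  rows <- if (identical(pop, "ALL")) seq_len(n_haps(haps))
          else which(haps$pop == pop)
  if (length(rows) < 2L)
    stop("population subset `", pop, "` has fewer than 2 haplotypes",
         call. = FALSE)
  f <- colMeans(haps$alleles[rows, , drop = FALSE])
  data.frame(site = seq_len(n_sites(haps)),
             position_bp = haps$positions_bp,
             freq = f, maf = pmin(f, 1 - f))
}

#' Target minor-allele-frequency histogram for array ascertainment
#'
#' Describes the MAF spectrum the designed array should match in the
#' ascertainment population, as `B` bins over `(0, 0.5]` with target
#' proportions. The shipped default up-weights common variants (5 equal
#' bins with proportions 0.10/0.15/0.20/0.25/0.30), emulating the
#' common-variant ascertainment bias of genotyping arrays designed from
#' European sequencing panels.
#'
#' @param edges Increasing numeric vector of `B + 1` bin edges spanning
#'   `[0, 0.5]`; bins are lower-open, upper-closed.
#' @param proportions Numeric vector of `B` non-negative proportions
#'   summing to 1 within 1e-9.
#' @return An object of class `maf_histogram`.
#' @export
maf_histogram <- function(edges = seq(0, 0.5, by = 0.1),
                          proportions = c(0.10, 0.15, 0.20, 0.25, 0.30)) {
  if (length(edges) != length(proportions) + 1L)
    stop("`edges` must have one more entry than `proportions`",
         call. = FALSE)
  if (any(diff(edges) <= 0) || edges[1L] < 0 ||
      edges[length(edges)] > 0.5)
    stop("`edges` must be strictly increasing within [0, 0.5]",
         call. = FALSE)
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-9)
    stop("`proportions` must be non-negative and sum to 1", call. = FALSE)
  structure(list(edges = edges, proportions = proportions),
            class = "maf_histogram")
}

## integer quotas summing to M by largest-remainder apportionment
largest_remainder <- function(weights, M) {
  raw <- weights / sum(weights) * M
  quota <- floor(raw)
  short <- M - sum(quota)
  if (short > 0) {
    extra <- order(raw - quota, decreasing = TRUE)[seq_len(short)]
    quota[extra] <- quota[extra] + 1
  }
  as.integer(quota)
}

#' Select array sites matching a MAF spectrum and mean spacing
#'
#' Emulates array design under ascertainment bias: chooses
#' `M = round(length_bp / target_mean_spacing_bp)` sites whose
#' minor-allele-frequency spectrum in the ascertainment population matches
#' a target histogram and whose mean physical spacing approximates the
#' target. Sites monomorphic in the ascertainment population are
#' ineligible. Per-bin quotas are apportioned by largest remainder (with
#' proportional redistribution when a bin runs out of candidates); within
#' each bin sites are drawn uniformly, rejecting draws (up to 50 attempts)
#' that fall closer than a quarter of the target spacing to an
#' already-selected site, then accepting unconditionally.
#'
#' @param haps A [haplotype_set()] providing the candidate sites.
#' @param chrom The [chromosome_spec()].
#' @param ascertainment_pop Population whose MAF drives ascertainment
#'   (e.g. `"EUR"`), or `"ALL"`.
#' @param target_mean_spacing_bp Target mean inter-marker distance (bp).
#' @param histogram A [maf_histogram()]; default [maf_histogram()].
#' @param seed Integer seed; selection is deterministic given the seed.
#' @return An object of class `array_scheme` with sorted
#'   `typed_site_indices`, the ascertainment targets, the seed, and the
#'   realized spacing / bin proportions.
#' @export
ascertain_sites <- function(haps, chrom, ascertainment_pop = "EUR",
                            target_mean_spacing_bp,
                            histogram = maf_histogram(), seed) {
  stopifnot(inherits(haps, "haplotype_set"),
            inherits(chrom, "chromosome_spec"),
            inherits(histogram, "maf_histogram"))
  M <- round(chrom$length_bp / target_mean_spacing_bp)
  maf <- site_frequencies(haps, ascertainment_pop)$maf
  bin_of <- findInterval(maf, histogram$edges, left.open = TRUE)
  bin_of[maf == 0] <- 0L # monomorphic in ascertainment pop: ineligible
  B <- length(histogram$proportions)
  avail <- tabulate(bin_of, nbins = B)
  if (sum(avail) < M) {
    occ <- paste(sprintf("bin%d=%d", seq_len(B), avail), collapse = ", ")
    stop("only ", sum(avail), " eligible candidates for M = ", M,
         " array sites (", occ, ")", call. = FALSE)
  }
  set.seed(as.integer(seed))

  quota <- largest_remainder(histogram$proportions, M)
  ## redistribute shortfall from exhausted bins to bins with spare capacity
  for (it in seq_len(B + 1L)) {
    quota <- pmin(quota, avail)
    deficit <- M - sum(quota)
    if (deficit == 0L) break
    spare <- avail - quota
    open <- spare > 0
    add <- largest_remainder(histogram$proportions[open] + 1e-12, deficit)
    add <- pmin(add, spare[open])
    quota[open] <- quota[open] + add
  }
  if (sum(quota) != M)
    stop("quota redistribution failed to allocate all sites", call. = FALSE)

  min_gap <- target_mean_spacing_bp / 4
  pos <- haps$positions_bp
  selected <- integer(0)
  sel_pos <- numeric(0)
  too_close <- function(p) {
    if (!length(sel_pos)) return(FALSE)
    i <- findInterval(p, sel_pos)
    (i >= 1L && p - sel_pos[i] < min_gap) ||
      (i < length(sel_pos) && sel_pos[i + 1L] - p < min_gap)
  }
  for (b in seq_len(B)) {
    cand <- which(bin_of == b)
    for (j in seq_len(quota[b])) {
      pick <- NA_integer_
      for (attempt in seq_len(50L)) {
        pick <- cand[sample.int(length(cand), 1L)]
        if (!too_close(pos[pick])) break
      }
      selected <- c(selected, pick)
      ins <- findInterval(pos[pick], sel_pos)
      sel_pos <- append(sel_pos, pos[pick], after = ins)
      cand <- cand[cand != pick]
    }
  }
  selected <- sort(selected)

  realized_prop <- tabulate(bin_of[selected], nbins = B) / M
  realized_spacing <- if (length(selected) > 1L)
    mean(diff(pos[selected])) else NA_real_
  structure(list(typed_site_indices = selected,
                 ascertainment_pop = ascertainment_pop,
                 target_mean_spacing_bp = target_mean_spacing_bp,
                 histogram = histogram,
                 seed = as.integer(seed),
                 realized_proportions = realized_prop,
                 realized_mean_spacing_bp = realized_spacing),
            class = "array_scheme")
}

#' @export
print.array_scheme <- function(x, ...) {
  cat(sprintf(paste0("array_scheme: %d typed sites (%s-ascertained), ",
                     "mean spacing %.0f bp (target %.0f)\n"),
              length(x$typed_site_indices), x$ascertainment_pop,
              x$realized_mean_spacing_bp, x$target_mean_spacing_bp))
  invisible(x)
}

#' Split a haplotype set into typed (array) and held-out sites
#'
#' The typed and held-out partitions cover the original site set exactly
#' once; the held-out sites serve as imputation truth.
#'
#' @param haps A [haplotype_set()].
#' @param scheme An [ascertain_sites()] scheme, or an integer vector of
#'   typed site indices.
#' @return List with `typed` and `heldout` haplotype sets and the index
#'   vectors `typed_idx`, `heldout_idx`.
#' @export
mask_to_array <- function(haps, scheme) {
  stopifnot(inherits(haps, "haplotype_set"))
  idx <- if (inherits(scheme, "array_scheme"))
    scheme$typed_site_indices else as.integer(scheme)
  if (anyDuplicated(idx))
    stop("typed site indices must be unique", call. = FALSE)
  if (length(idx) && (min(idx) < 1L || max(idx) > n_sites(haps)))
    stop("typed site index out of range for this haplotype set",
         call. = FALSE)
  idx <- sort(idx)
  comp <- setdiff(seq_len(n_sites(haps)), idx)
  list(typed = hs_sites(haps, idx),
       heldout = hs_sites(haps, comp),
       typed_idx = idx, heldout_idx = comp)
}
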