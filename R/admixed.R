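#' Configure a single-pulse admixture event
#'
#' Models a population formed by one admixture pulse `generations_ago`
#' generations in the past. Under the standard pulse approximation, each
#' admixed haplotype is a mosaic whose ancestry-switch points form a
#' Poisson process of rate `generations_ago` per Morgan; the ancestry of
#' each segment is drawn independently from `proportions` (a switch may
#' redraw the same ancestry), and the sequence of each segment is copied
#' from one uniformly chosen source haplotype of that ancestry.
#'
#' @param proportions Named numeric vector of admixture proportions for
#'   `AFR`, `EUR`, `NAT` (entries in `[0, 1]`, summing to 1 within 1e-9).
#'   Default is the Latin American mix 1/6 African, 1/3 European,
#'   1/2 Native American.
#' @param generations_ago Integer `g >= 1`; default 12.
#' @param n_individuals Number of admixed individuals to generate.
#' @return An object of class `admixture_config`.
#' @export
admixture_config <- function(proportions = c(AFR = 1 / 6, EUR = 1 / 3,
                                             NAT = 1 / 2),
                             generations_ago = 12L, n_individuals) {
  if (is.null(names(proportions)) || anyDuplicated(names(proportions)))
    stop("`proportions` must be uniquely named by ancestry", call. = FALSE)
  if (any(proportions < 0) || any(proportions > 1))
    stop("proportions must lie in [0, 1]", call. = FALSE)
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("proportions must sum to 1", call. = FALSE)
  if (generations_ago < 1L)
    stop("`generations_ago` must be >= 1", call. = FALSE)
  if (n_individuals < 1L)
    stop("`n_individuals` must be >= 1", call. = FALSE)
  structure(list(proportions = proportions,
                 generations_ago = as.integer(generations_ago),
                 n_individuals = as.integer(n_individuals)),
            class = "admixture_config")
}

#' Simulate an admixed cohort as an ancestry mosaic with truth tracts
#'
#' Generates `2 * n_individuals` admixed haplotypes by copying segments
#' from the source haplotypes, together with the exact ancestry tract of
#' every haplotype. Tract intervals are 0-based, half-open `[start, end)`
#' and tile the chromosome exactly; adjacent same-ancestry segments are
#' merged in the returned tracks (donor choice still changes at every
#' Poisson switch point).
#'
#' @param sources A [haplotype_set()] containing the source populations
#'   (at least 2 haplotypes for every ancestry with positive proportion).
#' @param cfg An [admixture_config()].
#' @param chrom The [chromosome_spec()] the sources were simulated on.
#' @param seed Integer seed.
#' @return A list with components `haps` (a `haplotype_set` of the admixed
#'   cohort, population label `"ADM"`) and `tracks` (an `ancestry_tracks`
#'   data frame, see [ancestry_tracks()]).
#' @export
simulate_admixed <- function(sources, cfg, chrom, seed) {
  stopifnot(inherits(sources, "haplotype_set"),
            inherits(cfg, "admixture_config"),
            inherits(chrom, "chromosome_spec"))
  props <- cfg$proportions
  anc_labels <- names(props)
  donor_rows <- lapply(anc_labels, function(a) which(sources$pop == a))
  names(donor_rows) <- anc_labels
  for (a in anc_labels)
    if (props[[a]] > 0 && length(donor_rows[[a]]) < 2L)
      stop("ancestry ", a, " has positive proportion but fewer than 2 ",
           "source haplotypes", call. = FALSE)
  set.seed(as.integer(seed))

  L <- n_sites(sources)
  n_hap <- 2L * cfg$n_individuals
  total_M <- chrom_morgans(chrom)
  pos_bp <- sources$positions_bp
  alleles <- matrix(0L, n_hap, L)
  track_list <- vector("list", n_hap)
  ind <- paste0("ADM_", ceiling(seq_len(n_hap) / 2))
  hap_labels <- paste0(ind, ".", rep(1:2, length.out = n_hap))

  for (h in seq_len(n_hap)) {
    n_switch <- stats::rpois(1L, cfg$generations_ago * total_M)
    br_cM <- sort(stats::runif(n_switch, 0, total_M * 100))
    br_bp <- unique(pmin(pmax(floor(cM_to_bp(chrom, br_cM)), 1),
                         chrom$length_bp - 1))
    starts <- c(0, br_bp)
    ends <- c(br_bp, chrom$length_bp)
    n_seg <- length(starts)
    seg_anc <- sample(anc_labels, n_seg, replace = TRUE, prob = props)
    seg_of_site <- findInterval(pos_bp, starts)
    for (s in seq_len(n_seg)) {
      donor <- donor_rows[[seg_anc[s]]]
      donor <- donor[sample.int(length(donor), 1L)]
      in_seg <- which(seg_of_site == s)
      if (length(in_seg))
        alleles[h, in_seg] <- sources$alleles[donor, in_seg]
    }
    keep <- c(TRUE, seg_anc[-1L] != seg_anc[-n_seg])
    m_starts <- starts[keep]
    track_list[[h]] <- data.frame(
      hap = hap_labels[h], ind = ind[h],
      start_bp = m_starts,
      end_bp = c(m_starts[-1L], chrom$length_bp),
      ancestry = seg_anc[keep],
      stringsAsFactors = FALSE)
  }

  haps <- haplotype_set(alleles, pos_bp, sources$positions_cM,
                        pop = "ADM", ind = ind, hap_labels = hap_labels)
  tracks <- ancestry_tracks(do.call(rbind, track_list), chrom$length_bp)
  list(haps = haps, tracks = tracks)
}

#' Validate and normalize ancestry tracts
#'
#' Ancestry tracks are a long-format table with one row per tract:
#' columns `hap` (haplotype id), `ind` (individual id), `start_bp`,
#' `end_bp` (0-based, half-open) and `ancestry`. Per haplotype the tracts
#' must tile `[0, length_bp)` exactly; adjacent tracts with the same
#' ancestry are merged.
#'
#' @param df Data frame with the columns above.
#' @param length_bp Chromosome length the tracts must tile.
#' @return The normalized data frame with class `ancestry_tracks` and
#'   attribute `length_bp`.
#' @export
ancestry_tracks <- function(df, length_bp) {
  required <- c("hap", "ind", "start_bp", "end_bp", "ancestry")
  if (!all(required %in% names(df)))
    stop("tracks need columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  df <- df[order(df$hap, df$start_bp), required, drop = FALSE]
  pieces <- lapply(split(df, df$hap), function(d) {
    if (d$start_bp[1L] != 0 || d$end_bp[nrow(d)] != length_bp ||
        (nrow(d) > 1 && any(d$start_bp[-1L] != d$end_bp[-nrow(d)])))
      stop("tracts of haplotype ", d$hap[1L],
           " do not tile [0, length_bp) exactly", call. = FALSE)
    if (any(d$end_bp <= d$start_bp))
      stop("empty or inverted tract on haplotype ", d$hap[1L],
           call. = FALSE)
    keep <- c(TRUE, d$ancestry[-1L] != d$ancestry[-nrow(d)])
    merged <- d[keep, , drop = FALSE]
    merged$end_bp <- c(merged$start_bp[-1L], length_bp)
    merged
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  structure(out, length_bp = length_bp,
            class = c("ancestry_tracks", "data.frame"))
}

#' Genome fractions of each ancestry from truth tracts
#'
#' Computes, per haplotype, the fraction of physical chromosome length
#' covered by each ancestry; per individual, the mean of its two
#' haplotypes; and the cohort mean across individuals. Fractions sum to 1
#' per haplotype.
#'
#' @param tracks An [ancestry_tracks()] object.
#' @return A list with data frame `per_haplotype`, data frame
#'   `per_individual` and named numeric `cohort_mean`.
#' @export
ancestry_fractions <- function(tracks) {
  stopifnot(inherits(tracks, "ancestry_tracks"))
  length_bp <- attr(tracks, "length_bp")
  ancs <- sort(unique(tracks$ancestry))
  len <- tapply((tracks$end_bp - tracks$start_bp) / length_bp,
                list(tracks$hap, factor(tracks$ancestry, levels = ancs)),
                sum, default = 0)
  per_hap <- data.frame(hap = rownames(len), as.data.frame(unclass(len)),
                        row.names = NULL, stringsAsFactors = FALSE)
  ind_of <- tracks$ind[match(per_hap$hap, tracks$hap)]
  per_ind_mat <- apply(len, 2, function(col) tapply(col, ind_of, mean))
  if (is.null(dim(per_ind_mat)))
    per_ind_mat <- matrix(per_ind_mat, nrow = 1,
                          dimnames = list(unique(ind_of), ancs))
  per_ind <- data.frame(ind = rownames(per_ind_mat),
                        as.data.frame(per_ind_mat),
                        row.names = NULL, stringsAsFactors = FALSE)
  cohort <- colMeans(per_ind_mat)
  list(per_haplotype = per_hap, per_individual = per_ind,
       cohort_mean = cohort)
}
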