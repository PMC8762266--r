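#' Minor-allele-frequency bins for stratified evaluation
#'
#' Frequency classes are given as strictly decreasing breakpoints on
#' `(0, 0.5]`. The default reproduces the three standard classes:
#' common `[0.05, 0.5]`, low `[0.01, 0.05)` and rare `[0.003, 0.01)`;
#' observations with MAF below the lowest breakpoint are excluded. The
#' boundary convention (a breakpoint belongs to the class above it, so
#' MAF = 0.05 is "common") is fixed and recorded here.
#'
#' @param breaks Strictly decreasing numeric breakpoints within
#'   `(0, 0.5]`, starting at 0.5.
#' @param labels Class labels, one per interval (length
#'   `length(breaks) - 1`), ordered from the most common class down.
#' @return An object of class `freq_bins`.
#' @export
freq_bins <- function(breaks = c(0.5, 0.05, 0.01, 0.003),
                      labels = c("common", "low", "rare")) {
  if (any(diff(breaks) >= 0) || any(breaks <= 0) || any(breaks > 0.5))
    stop("`breaks` must be strictly decreasing within (0, 0.5]",
         call. = FALSE)
  if (length(labels) != length(breaks) - 1L)
    stop("need one label per interval", call. = FALSE)
  structure(list(breaks = breaks, labels = as.character(labels)),
            class = "freq_bins")
}

#' Assign minor-allele frequencies to frequency classes
#'
#' Binning is half-open `[lower, upper)` with the top class closed at
#' 0.5; MAF below the lowest breakpoint returns `"EXCLUDED"`.
#'
#' @param maf Numeric vector of minor-allele frequencies in `[0, 0.5]`.
#' @param bins A [freq_bins()].
#' @return Character vector of class labels (or `"EXCLUDED"`).
#' @export
maf_bin <- function(maf, bins = freq_bins()) {
  stopifnot(inherits(bins, "freq_bins"))
  if (anyNA(maf) || any(maf < 0) || any(maf > 0.5))
    stop("MAF values must lie in [0, 0.5]", call. = FALSE)
  edges <- rev(bins$breaks)            # ascending
  labels_asc <- rev(bins$labels)
  idx <- findInterval(maf, edges, rightmost.closed = TRUE)
  out <- rep("EXCLUDED", length(maf))
  out[idx > 0] <- labels_asc[idx[idx > 0]]
  out
}

## ancestry label of one haplotype's tract at each queried position
tract_label_at <- function(d, site_bp, length_bp) {
  if (any(site_bp < 0) || any(site_bp >= length_bp))
    stop("site position outside the chromosome", call. = FALSE)
  d <- d[order(d$start_bp), , drop = FALSE]
  d$ancestry[findInterval(site_bp, d$start_bp)]
}

#' Local-ancestry diplotype of an individual at given sites
#'
#' Looks up the tract containing each site on the individual's two
#' haplotypes (half-open `[start, end)` semantics: a site exactly at a
#' tract boundary belongs to the tract beginning there) and returns the
#' normalized unordered pair, e.g. `"EUR_NAT"` (labels sorted
#' alphabetically, so never `"NAT_EUR"`).
#'
#' @param tracks An [ancestry_tracks()] object.
#' @param individual Individual identifier present in `tracks`.
#' @param site_bp Vector of 0-based site positions.
#' @return Character vector of diplotype labels.
#' @export
diplotype_at <- function(tracks, individual, site_bp) {
  stopifnot(inherits(tracks, "ancestry_tracks"))
  length_bp <- attr(tracks, "length_bp")
  rows <- tracks[tracks$ind == individual, , drop = FALSE]
  haps <- unique(rows$hap)
  if (length(haps) != 2L)
    stop("individual ", individual,
         " does not have exactly 2 haplotypes in the tracks",
         call. = FALSE)
  a <- tract_label_at(rows[rows$hap == haps[1L], ], site_bp, length_bp)
  b <- tract_label_at(rows[rows$hap == haps[2L], ], site_bp, length_bp)
  paste(pmin(a, b), pmax(a, b), sep = "_")
}

#' Long-format stratification of (individual, site) observations
#'
#' Assigns every combination of the given individuals and sites to a
#' local-ancestry diplotype and a MAF class.
#'
#' @param tracks An [ancestry_tracks()] covering the individuals.
#' @param individuals Individual identifiers.
#' @param site_bp 0-based positions of the evaluated sites.
#' @param maf Truth minor-allele frequency per site (same length as
#'   `site_bp`).
#' @param bins A [freq_bins()].
#' @return Data frame with columns `individual`, `site_bp`, `diplotype`,
#'   `maf`, `bin`.
#' @export
stratify_observations <- function(tracks, individuals, site_bp, maf,
                                  bins = freq_bins()) {
  if (length(maf) != length(site_bp))
    stop("`maf` must align with `site_bp`", call. = FALSE)
  bin <- maf_bin(maf, bins)
  out <- lapply(individuals, function(id)
    data.frame(individual = id, site_bp = site_bp,
               diplotype = diplotype_at(tracks, id, site_bp),
               maf = maf, bin = bin, stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
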