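#' Phased haplotype matrix with site coordinates
#'
#' The central container of the package: an `H x L` binary matrix of phased
#' haplotypes (rows) over `L` biallelic sites (columns), with physical
#' (0-based bp) and genetic (cM) coordinates per site, and population /
#' individual labels per haplotype. Consecutive haplotype pairs
#' `(2i - 1, 2i)` form individual `i`.
#'
#' @param alleles Integer matrix (`H x L`) of 0/1 alleles.
#' @param positions_bp Strictly increasing integer vector of length `L`
#'   (0-based base-pair positions).
#' @param positions_cM Non-decreasing numeric vector of length `L` (cM).
#' @param pop Character vector of length `H`: population label per
#'   haplotype (e.g. `"AFR"`, `"EUR"`, `"NAT"`, `"ADM"`).
#' @param ind Character vector of length `H`: individual identifier per
#'   haplotype; defaults to pairing consecutive haplotypes.
#' @param hap_labels Character vector of length `H` of unique haplotype
#'   identifiers; defaults to `<ind>.1` / `<ind>.2`.
#' @return An object of class `haplotype_set`.
#' @export
haplotype_set <- function(alleles, positions_bp, positions_cM, pop,
                          ind = NULL, hap_labels = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  H <- nrow(alleles); L <- ncol(alleles)
  if (L != length(positions_bp) || L != length(positions_cM))
    stop("site coordinate vectors must match the number of columns",
         call. = FALSE)
  if (anyNA(alleles) || !all(alleles == 0L | alleles == 1L))
    stop("alleles must be 0/1 with no missing values", call. = FALSE)
  if (L > 1 && any(diff(positions_bp) <= 0))
    stop("`positions_bp` must be strictly increasing", call. = FALSE)
  if (L > 1 && any(diff(positions_cM) < 0))
    stop("`positions_cM` must be non-decreasing", call. = FALSE)
  if (length(pop) == 1L) pop <- rep(pop, H)
  if (length(pop) != H)
    stop("`pop` must have one entry per haplotype", call. = FALSE)
  if (is.null(ind)) {
    if (H %% 2L != 0L)
      stop("default individual pairing requires an even haplotype count",
           call. = FALSE)
    ind <- paste0(pop, "_", ceiling(seq_len(H) / 2))
  }
  if (length(ind) != H)
    stop("`ind` must have one entry per haplotype", call. = FALSE)
  if (is.null(hap_labels)) {
    hap_labels <- stats::ave(ind, ind, FUN = function(z)
      paste0(z, ".", seq_along(z)))
  }
  if (anyDuplicated(hap_labels))
    stop("haplotype labels must be unique", call. = FALSE)
  structure(list(alleles = alleles,
                 positions_bp = as.numeric(positions_bp),
                 positions_cM = as.numeric(positions_cM),
                 pop = as.character(pop),
                 ind = as.character(ind),
                 hap_labels = as.character(hap_labels)),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d haplotypes (%d individuals) x %d sites\n",
              n_haps(x), length(unique(x$ind)), n_sites(x)))
  tab <- table(x$pop)
  cat("  populations:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of haplotypes in a haplotype set
#' @param x A `haplotype_set`.
#' @export
n_haps <- function(x) nrow(x$alleles)

#' Number of sites in a haplotype set
#' @param x A `haplotype_set`.
#' @export
n_sites <- function(x) ncol(x$alleles)

#' Restrict a haplotype set to a subset of sites
#' @param x A `haplotype_set`.
#' @param idx Site column indices (kept in the given order; must be
#'   increasing to preserve coordinate ordering).
#' @export
hs_sites <- function(x, idx) {
  idx <- as.integer(idx)
  if (length(idx) && (min(idx) < 1L || max(idx) > n_sites(x)))
    stop("site index out of range", call. = FALSE)
  haplotype_set(x$alleles[, idx, drop = FALSE],
                x$positions_bp[idx], x$positions_cM[idx],
                x$pop, x$ind, x$hap_labels)
}

#' Restrict a haplotype set to a subset of haplotypes
#' @param x A `haplotype_set`.
#' @param idx Haplotype row indices.
#' @export
hs_haps <- function(x, idx) {
  idx <- as.integer(idx)
  if (length(idx) && (min(idx) < 1L || max(idx) > n_haps(x)))
    stop("haplotype index out of range", call. = FALSE)
  haplotype_set(x$alleles[idx, , drop = FALSE],
                x$positions_bp, x$positions_cM,
                x$pop[idx], x$ind[idx], x$hap_labels[idx])
}

#' Restrict a haplotype set to whole individuals
#' @param x A `haplotype_set`.
#' @param ids Individual identifiers to keep.
#' @export
hs_individuals <- function(x, ids) {
  missing_ids <- setdiff(ids, x$ind)
  if (length(missing_ids))
    stop("individual(s) not present: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  hs_haps(x, which(x$ind %in% ids))
}

#' Stack two haplotype sets over the same sites
#'
#' Both sets must carry identical site coordinates; haplotypes of `y` are
#' appended below those of `x` (e.g. to add reference genomes to a panel).
#'
#' @param x,y `haplotype_set` objects with identical site coordinates.
#' @export
hs_bind <- function(x, y) {
  if (!identical(x$positions_bp, y$positions_bp))
    stop("haplotype sets are defined on different site sets", call. = FALSE)
  labs <- c(x$hap_labels, y$hap_labels)
  if (anyDuplicated(labs))
    stop("haplotype labels collide between the two sets", call. = FALSE)
  haplotype_set(rbind(x$alleles, y$alleles),
                x$positions_bp, x$positions_cM,
                c(x$pop, y$pop), c(x$ind, y$ind), labs)
}
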