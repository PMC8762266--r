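#' Merge two phased reference panels
#'
#' Two merge strategies are supported. `intersect` restricts both panels
#' to their common sites (matched on physical position) and stacks the
#' haplotypes. `cross_impute` takes the site union: for sites present in
#' only one panel, every haplotype of the other panel is imputed at those
#' sites with the copying HMM (using the shared sites as typed input) and
#' the filled allele is hard-called at probability 0.5, ties going to
#' allele 0. Hard-calling keeps the merged panel strictly binary; the
#' price is that imputation uncertainty in the filled sites is silently
#' committed, which is exactly the mechanism by which cross-imputation
#' can dilute accuracy at sites private to the smaller panel.
#'
#' @param panel_a,panel_b [haplotype_set()] panels on the same chromosome
#'   and coordinate system.
#' @param mode `"intersect"` or `"cross_impute"`.
#' @param params An [ls_params()] used for cross-imputation.
#' @return A merged [haplotype_set()] with `H_A + H_B` haplotypes.
#' @export
merge_panels <- function(panel_a, panel_b,
                         mode = c("intersect", "cross_impute"),
                         params = ls_params()) {
  stopifnot(inherits(panel_a, "haplotype_set"),
            inherits(panel_b, "haplotype_set"))
  mode <- match.arg(mode)
  pos_a <- panel_a$positions_bp
  pos_b <- panel_b$positions_bp
  common <- intersect(pos_a, pos_b)
  if (mode == "intersect") {
    if (!length(common))
      stop("panels share no sites; cannot merge by intersection",
           call. = FALSE)
    a <- hs_sites(panel_a, match(common, pos_a))
    b <- hs_sites(panel_b, match(common, pos_b))
    return(hs_bind(a, b))
  }
  union_pos <- sort(union(pos_a, pos_b))
  L <- length(union_pos)
  cM <- numeric(L)
  ia <- match(union_pos, pos_a)
  ib <- match(union_pos, pos_b)
  cM[!is.na(ia)] <- panel_a$positions_cM[ia[!is.na(ia)]]
  cM[is.na(ia)] <- panel_b$positions_cM[ib[is.na(ia)]]

  fill <- function(donor, other, idx_donor, idx_other) {
    ## donor: panel providing haplotypes to lift onto the union sites;
    ## other: panel used as imputation reference for the missing sites
    out <- matrix(0L, n_haps(donor), L)
    present <- !is.na(idx_donor)
    out[, present] <- donor$alleles[, idx_donor[present], drop = FALSE]
    missing <- which(!present)
    if (!length(missing)) return(out)
    shared_u <- which(present & !is.na(idx_other))
    if (!length(shared_u))
      stop("panels share no sites; cross-imputation impossible",
           call. = FALSE)
    other_on_union <- matrix(0L, n_haps(other), L)
    other_on_union[, !is.na(idx_other)] <-
      other$alleles[, idx_other[!is.na(idx_other)], drop = FALSE]
    for (h in seq_len(n_haps(donor))) {
      gamma <- ls_posteriors(out[h, shared_u],
                             other_on_union[, shared_u, drop = FALSE],
                             cM[shared_u], params)
      p1 <- interpolate_alleles(gamma, other_on_union, shared_u, cM,
                                params$lambda)
      out[h, missing] <- as.integer(p1[missing] > 0.5)
    }
    out
  }
  alleles_a <- fill(panel_a, panel_b, ia, ib)
  alleles_b <- fill(panel_b, panel_a, ib, ia)
  haplotype_set(rbind(alleles_a, alleles_b), union_pos, cM,
                c(panel_a$pop, panel_b$pop),
                c(panel_a$ind, panel_b$ind),
                c(panel_a$hap_labels, panel_b$hap_labels))
}

#' Leave-one-out imputation of individuals contained in a panel
#'
#' For every requested individual, its two haplotypes are removed from
#' the reference panel, the individual is masked down to the typed sites,
#' and its genotypes are imputed at every panel site against the reduced
#' reference. This mirrors the standard evaluation design where the
#' target cohort is itself part of the reference resource.
#'
#' @param panel A [haplotype_set()] containing the cohort.
#' @param cohort_inds Individual identifiers to impute (must be present
#'   in `panel`).
#' @param scheme An [ascertain_sites()] scheme or integer vector of typed
#'   site indices into `panel`'s sites.
#' @param params An [ls_params()].
#' @return A [genotype_probs()] over all panel sites.
#' @export
leave_one_out_impute <- function(panel, cohort_inds, scheme,
                                 params = ls_params()) {
  stopifnot(inherits(panel, "haplotype_set"))
  typed_idx <- if (inherits(scheme, "array_scheme"))
    scheme$typed_site_indices else sort(as.integer(scheme))
  missing_ids <- setdiff(cohort_inds, panel$ind)
  if (length(missing_ids))
    stop("individual(s) absent from panel: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  L <- n_sites(panel)
  N <- length(cohort_inds)
  p_AA <- p_Aa <- p_aa <- matrix(0, N, L)
  for (i in seq_len(N)) {
    rows <- which(panel$ind == cohort_inds[i])
    if (length(rows) != 2L)
      stop("individual ", cohort_inds[i],
           " does not have exactly 2 haplotypes in the panel",
           call. = FALSE)
    ref <- hs_haps(panel, setdiff(seq_len(n_haps(panel)), rows))
    gp <- impute_individual(panel$alleles[rows[1L], typed_idx],
                            panel$alleles[rows[2L], typed_idx],
                            ref, typed_idx, params)
    p_AA[i, ] <- gp$p_AA; p_Aa[i, ] <- gp$p_Aa; p_aa[i, ] <- gp$p_aa
  }
  genotype_probs(p_AA, p_Aa, p_aa, panel$positions_bp, cohort_inds)
}
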