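#' Write phased haplotypes to a VCF (v4.2)
#'
#' Exports a [haplotype_set()] as phased biallelic GT records. Internal
#' coordinates are 0-based half-open; VCF POS is 1-based, so positions
#' are shifted by +1 on write (and back on read). Population labels are
#' preserved in `##SAMPLE` meta lines. Files are bgzip-compressed by the
#' vcfR writer; use a `.vcf.gz` filename.
#'
#' @param haps A [haplotype_set()].
#' @param file Output path (`.vcf.gz`).
#' @param chrom Optional [chromosome_spec()] for the contig length
#'   header.
#' @param contig Contig name written to CHROM (default `"chr1"`).
#' @return The file path, invisibly.
#' @importClassesFrom vcfR vcfR
#' @export
write_haplotype_vcf <- function(haps, file, chrom = NULL,
                                contig = "chr1") {
  stopifnot(inherits(haps, "haplotype_set"))
  inds <- unique(haps$ind)
  contig_len <- if (is.null(chrom)) max(haps$positions_bp) + 1 else
    chrom$length_bp
  sample_meta <- vapply(inds, function(id) {
    pop <- haps$pop[match(id, haps$ind)]
    sprintf("##SAMPLE=<ID=%s,Population=%s>", id, pop)
  }, character(1))
  meta <- c("##fileformat=VCFv4.2",
            "##source=admiximpute",
            sprintf("##contig=<ID=%s,length=%.0f>", contig, contig_len),
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            sample_meta)
  L <- n_sites(haps)
  fix <- cbind(CHROM = rep(contig, L),
               POS = sprintf("%.0f", haps$positions_bp + 1),
               ID = rep(".", L), REF = rep("A", L), ALT = rep("T", L),
               QUAL = rep(".", L), FILTER = rep(".", L),
               INFO = rep(".", L))
  gt_cols <- vapply(inds, function(id) {
    rows <- which(haps$ind == id)
    paste0(haps$alleles[rows[1L], ], "|", haps$alleles[rows[2L], ])
  }, character(L))
  gt <- cbind(FORMAT = rep("GT", L), gt_cols)
  colnames(gt) <- c("FORMAT", inds)
  v <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = file)
  invisible(file)
}

#' Read phased haplotypes from a VCF
#'
#' Inverse of [write_haplotype_vcf()]: expects biallelic records with
#' phased GT. Population labels are recovered from `##SAMPLE` meta lines
#' when present, else set to `"ALL"`.
#'
#' @param file Path to a `.vcf` / `.vcf.gz` file.
#' @param chrom Optional [chromosome_spec()] used to compute genetic
#'   positions; defaults to a uniform 1 cM/Mb map over the contig.
#' @return A [haplotype_set()].
#' @export
read_haplotype_vcf <- function(file, chrom = NULL) {
  if (!file.exists(file))
    stop("VCF file not found: ", file, call. = FALSE)
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  pos <- as.numeric(vcfR::getPOS(v)) - 1
  gt <- vcfR::extract.gt(v, element = "GT")
  if (anyNA(gt))
    stop("malformed VCF ", file, ": missing GT entries", call. = FALSE)
  bad <- which(!grepl("^[01]\\|[01]$", gt))
  if (length(bad))
    stop("malformed VCF ", file, ": record ",
         ((bad[1L] - 1L) %% nrow(gt)) + 1L,
         " violates phased biallelic GT (\"a|b\" with a,b in 0/1)",
         call. = FALSE)
  inds <- colnames(gt)
  H <- 2L * length(inds)
  L <- nrow(gt)
  alleles <- matrix(0L, H, L)
  for (i in seq_along(inds)) {
    alleles[2L * i - 1L, ] <- as.integer(substr(gt[, i], 1L, 1L))
    alleles[2L * i, ] <- as.integer(substr(gt[, i], 3L, 3L))
  }
  pop_of <- rep("ALL", length(inds))
  sm <- grep("^##SAMPLE=", v@meta, value = TRUE)
  if (length(sm)) {
    ids <- sub(".*ID=([^,>]+).*", "\\1", sm)
    pops <- sub(".*Population=([^,>]+).*", "\\1", sm)
    hit <- match(inds, ids)
    pop_of[!is.na(hit)] <- pops[hit[!is.na(hit)]]
  }
  if (is.null(chrom)) {
    clen <- suppressWarnings(as.numeric(
      sub(".*length=([0-9]+).*", "\\1",
          grep("^##contig=", v@meta, value = TRUE)[1L])))
    if (!length(clen) || is.na(clen)) clen <- max(pos) + 1
    chrom <- chromosome_spec(clen)
  }
  haplotype_set(alleles, pos, bp_to_cM(chrom, pos),
                pop = rep(pop_of, each = 2L),
                ind = rep(inds, each = 2L))
}

#' Write imputed genotype probabilities to a VCF
#'
#' Exports a [genotype_probs()] with per-site INFO score in the INFO
#' column (`INFO=<value>`) and per-sample `GT:GP:DS` FORMAT fields (GT is
#' the maximum-probability genotype, unphased).
#'
#' @param gp A [genotype_probs()].
#' @param file Output path (`.vcf.gz`).
#' @param contig Contig name (default `"chr1"`).
#' @return The file path, invisibly.
#' @export
write_imputed_vcf <- function(gp, file, contig = "chr1") {
  stopifnot(inherits(gp, "genotype_probs"))
  L <- ncol(gp$p_AA)
  info <- info_scores(gp)
  ds <- dosages(gp)
  meta <- c("##fileformat=VCFv4.2",
            "##source=admiximpute",
            sprintf("##contig=<ID=%s,length=%.0f>", contig,
                    max(gp$positions_bp) + 1),
            "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"IMPUTE-style info score\">",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Best-guess genotype\">",
            "##FORMAT=<ID=GP,Number=3,Type=Float,Description=\"Genotype probabilities P(AA),P(Aa),P(aa)\">",
            "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Expected alternate allele dosage\">")
  fix <- cbind(CHROM = rep(contig, L),
               POS = sprintf("%.0f", gp$positions_bp + 1),
               ID = rep(".", L), REF = rep("A", L), ALT = rep("T", L),
               QUAL = rep(".", L), FILTER = rep(".", L),
               INFO = sprintf("INFO=%.6g", info))
  gts <- c("0/0", "0/1", "1/1")
  cols <- vapply(seq_along(gp$ind), function(i) {
    p <- rbind(gp$p_AA[i, ], gp$p_Aa[i, ], gp$p_aa[i, ])
    best <- max.col(t(p))
    sprintf("%s:%.6g,%.6g,%.6g:%.6g",
            gts[best], p[1L, ], p[2L, ], p[3L, ], ds[i, ])
  }, character(L))
  gt <- cbind(FORMAT = rep("GT:GP:DS", L), cols)
  colnames(gt) <- c("FORMAT", gp$ind)
  v <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = file)
  invisible(file)
}

#' Write ancestry tracks to a BED-like TSV
#'
#' Four tab-separated columns with a header: `haplotype_id`, `start_bp`
#' (0-based), `end_bp` (exclusive), `ancestry`. Haplotype identifiers
#' follow the `<individual>.<1|2>` convention so the individual pairing
#' can be reconstructed on read.
#'
#' @param tracks An [ancestry_tracks()].
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
write_tracks_tsv <- function(tracks, file) {
  stopifnot(inherits(tracks, "ancestry_tracks"))
  out <- data.frame(haplotype_id = tracks$hap,
                    start_bp = sprintf("%.0f", tracks$start_bp),
                    end_bp = sprintf("%.0f", tracks$end_bp),
                    ancestry = tracks$ancestry)
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read ancestry tracks from a BED-like TSV
#'
#' @param file Path to a TSV written by [write_tracks_tsv()] (header
#'   required).
#' @param length_bp Chromosome length the tracts must tile.
#' @return An [ancestry_tracks()].
#' @export
read_tracks_tsv <- function(file, length_bp) {
  if (!file.exists(file))
    stop("tracks file not found: ", file, call. = FALSE)
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  required <- c("haplotype_id", "start_bp", "end_bp", "ancestry")
  if (!all(required %in% names(df)))
    stop("malformed tracks file ", file, ": header must name columns ",
         paste(required, collapse = ", "), call. = FALSE)
  ancestry_tracks(data.frame(hap = df$haplotype_id,
                             ind = sub("\\.[0-9]+$", "", df$haplotype_id),
                             start_bp = df$start_bp, end_bp = df$end_bp,
                             ancestry = df$ancestry,
                             stringsAsFactors = FALSE),
                  length_bp)
}

#' Write an array site list
#'
#' One 1-based bp position per line (plain text), plus a JSON sidecar
#' (`<file>.json`) with the scheme metadata (ascertainment population,
#' spacing and histogram targets, seed, realized statistics).
#'
#' @param scheme An [ascertain_sites()] scheme.
#' @param haps The [haplotype_set()] the scheme indexes into.
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
write_site_list <- function(scheme, haps, file) {
  stopifnot(inherits(scheme, "array_scheme"),
            inherits(haps, "haplotype_set"))
  pos1 <- haps$positions_bp[scheme$typed_site_indices] + 1
  writeLines(sprintf("%.0f", pos1), file)
  side <- scheme
  side$typed_site_indices <- NULL
  side$histogram <- unclass(side$histogram)
  jsonlite::write_json(unclass(side), paste0(file, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read an array site list back into site indices
#'
#' @param file Path to a site list written by [write_site_list()].
#' @param haps The [haplotype_set()] to match positions against.
#' @return Sorted integer vector of typed site indices.
#' @export
read_site_list <- function(file, haps) {
  if (!file.exists(file))
    stop("site list not found: ", file, call. = FALSE)
  pos1 <- suppressWarnings(as.numeric(readLines(file)))
  if (anyNA(pos1))
    stop("malformed site list ", file, ": line ",
         which(is.na(pos1))[1L], " is not a number", call. = FALSE)
  idx <- match(pos1 - 1, haps$positions_bp)
  if (anyNA(idx))
    stop("site list ", file, ": line ", which(is.na(idx))[1L],
         " names a position absent from the haplotype set",
         call. = FALSE)
  sort(idx)
}

#' Write a long-format accuracy table as TSV
#'
#' Numeric columns are serialized at full double precision so the table
#' round-trips exactly.
#'
#' @param table Accuracy table (data frame).
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
write_accuracy_tsv <- function(table, file) {
  out <- table
  for (cl in names(out)) {
    if (is.double(out[[cl]])) out[[cl]] <- sprintf("%.17g", out[[cl]])
  }
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read an accuracy table TSV
#'
#' @param file Path written by [write_accuracy_tsv()].
#' @return Data frame.
#' @export
read_accuracy_tsv <- function(file) {
  if (!file.exists(file))
    stop("accuracy table not found: ", file, call. = FALSE)
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  for (cl in c("r2", "mean_info", "delta_r2"))
    if (cl %in% names(df)) df[[cl]] <- as.numeric(df[[cl]])
  df
}

#' Read and validate a YAML run configuration
#'
#' @param file Path to a YAML file with the keys of [default_config()].
#' @return A validated configuration list.
#' @export
read_run_config <- function(file) {
  if (!file.exists(file))
    stop("config file not found: ", file, call. = FALSE)
  cfg <- yaml::read_yaml(file)
  cfg$array$histogram_proportions <-
    as.numeric(cfg$array$histogram_proportions)
  cfg$bins <- as.numeric(cfg$bins)
  validate_config(cfg)
}

#' Write a YAML run configuration
#'
#' @param cfg Configuration list.
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
write_run_config <- function(cfg, file) {
  yaml::write_yaml(cfg, file, precision = 15)
  invisible(file)
}

#' Write a JSON run manifest
#'
#' @param manifest Manifest list (resolved config, seeds, versions).
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
write_manifest <- function(manifest, file) {
  jsonlite::write_json(manifest, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
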