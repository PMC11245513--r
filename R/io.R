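#' Regional GWAS summary statistics for one query trait
#'
#' Container for the per-SNP summary data of a single query trait over a
#' genomic region that includes the query variant. Variant identifiers follow
#' the `chrom_pos_ref_alt` convention with the alternate allele as the effect
#' allele.
#'
#' @param snp_ids character vector of unique variant ids (`chrom_pos_ref_alt`).
#' @param beta per-SNP effect estimate (log odds ratio for case-control
#'   traits, standardized units for quantitative traits). May be `NULL` when
#'   `z` is supplied directly.
#' @param se standard error of `beta` (strictly positive where `beta` is
#'   present). May be `NULL` when `z` is supplied.
#' @param z per-SNP z-score; derived as `beta/se` when omitted.
#' @param maf minor allele frequency in (0, 0.5].
#' @param n total sample size (cases + controls for case-control traits).
#' @param s case fraction in (0, 1); ignored for quantitative traits.
#' @param trait_type `"cc"` (case-control) or `"quant"`.
#' @param query_index 1-based index of the query variant within `snp_ids`
#'   (`NA` allowed until a query variant is assigned).
#' @param trait_id label of the query trait.
#' @param chr,pos optional chromosome and 1-based position vectors; parsed
#'   from `snp_ids` when omitted.
#' @param pval two-sided p-values in (0, 1]; reconstructed from `z` via the
#'   standard normal tail when omitted.
#'
#' @return an object of class `region_summary`.
#' @export
region_summary <- function(snp_ids, beta = NULL, se = NULL, z = NULL,
                           maf = NULL, n = NULL, s = NULL,
                           trait_type = c("cc", "quant"),
                           query_index = NA_integer_, trait_id = "trait",
                           chr = NULL, pos = NULL, pval = NULL) {
  trait_type <- match.arg(trait_type)
  snp_ids <- as.character(snp_ids)
  Q <- length(snp_ids)
  if (Q < 2L) stop_validation("a region needs at least 2 SNPs, got ", Q)
  if (anyDuplicated(snp_ids)) {
    dup <- unique(snp_ids[duplicated(snp_ids)])
    stop_validation("duplicate snp ids: ", paste(dup, collapse = ", "))
  }
  if (is.null(z)) {
    if (is.null(beta) || is.null(se))
      stop_format("need either z or both beta and se")
    if (any(se <= 0, na.rm = TRUE)) stop_validation("se must be > 0")
    z <- beta / se
  }
  if (!all(is.finite(z))) stop_validation("z must be finite")
  if (is.null(pval)) pval <- 2 * stats::pnorm(-abs(z))
  if (is.null(chr) || is.null(pos)) {
    parts <- strsplit(snp_ids, "_", fixed = TRUE)
    ok <- lengths(parts) >= 2L
    chr <- chr %||% ifelse(ok, vapply(parts, `[`, "", 1L), NA_character_)
    pos <- pos %||% suppressWarnings(
      as.numeric(ifelse(ok, vapply(parts, `[`, "", 2L), NA)))
  }
  for (v in list(beta, se, maf, pval, chr, pos))
    if (!is.null(v) && length(v) != Q)
      stop_validation("all per-SNP vectors must have length Q = ", Q)
  if (!is.null(maf) && any(maf <= 0 | maf > 0.5, na.rm = TRUE))
    stop_validation("maf must lie in (0, 0.5]")
  if (!is.na(query_index) && (query_index < 1L || query_index > Q))
    stop_validation("query_index out of range")
  structure(list(
    snp_ids = snp_ids, chr = as.character(chr), pos = as.numeric(pos),
    beta = beta, se = se, z = as.numeric(z), pval = as.numeric(pval),
    maf = maf, n = n, s = if (trait_type == "cc") s else NULL,
    trait_type = trait_type, query_index = as.integer(query_index),
    trait_id = trait_id), class = "region_summary")
}

#' @export
print.region_summary <- function(x, ...) {
  cat(sprintf("<region_summary> trait '%s': %d SNPs (%s)\n", x$trait_id,
              length(x$snp_ids), x$trait_type))
  if (!is.na(x$query_index))
    cat(sprintf("  query variant: %s (index %d, z = %.2f)\n",
                x$snp_ids[x$query_index], x$query_index, x$z[x$query_index]))
  invisible(x)
}

#' Number of SNPs in a region
#' @param region a [region_summary()].
#' @export
n_snps <- function(region) length(region$snp_ids)

#' SNP-by-SNP LD correlation matrix
#'
#' @param r square numeric matrix of pairwise genotype correlations in
#'   \[-1, 1\] with unit diagonal.
#' @param snp_ids variant identifiers (same convention as
#'   [region_summary()]); taken from `dimnames(r)` when omitted.
#' @param regularize logical; shrink towards the identity,
#'   `r <- (1 - eps) r + eps I`, to guard positive semi-definiteness of
#'   finite-panel estimates.
#' @param eps shrinkage weight used when `regularize = TRUE`.
#' @return an object of class `ld_matrix` (the matrix with ids as dimnames).
#' @export
ld_matrix <- function(r, snp_ids = NULL, regularize = TRUE, eps = 1e-4) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop_validation("LD matrix must be square")
  snp_ids <- snp_ids %||% rownames(r)
  if (is.null(snp_ids) || length(snp_ids) != nrow(r))
    stop_validation("need one snp id per row")
  if (max(abs(r - t(r))) > 1e-8) stop_validation("LD matrix must be symmetric")
  if (any(abs(r) > 1 + 1e-8)) stop_validation("LD entries must lie in [-1, 1]")
  r <- (r + t(r)) / 2
  if (regularize) {
    r <- (1 - eps) * r
    diag(r) <- diag(r) + eps
  }
  diag(r) <- 1
  dimnames(r) <- list(snp_ids, snp_ids)
  class(r) <- c("ld_matrix", "matrix", "array")
  r
}

#' Read a GWAS summary table
#'
#' Reads a tab- or comma-delimited summary-statistics file (gzip handled
#' transparently) into a [region_summary()]. The file must name at least a
#' SNP id column and either `beta` + `se` or `z`. Rows with missing required
#' fields are dropped with a message.
#'
#' @param path file path.
#' @param dialect named character vector mapping canonical column names
#'   (`snp`, `chr`, `pos`, `beta`, `se`, `z`, `p`, `maf`, `n`, `s`, `type`)
#'   to the names used in the file, e.g. `c(snp = "rsid", p = "pvalue")`.
#' @param query id of the query variant (optional).
#' @param trait_id trait label; defaults to the file name.
#' @return a [region_summary()].
#' @export
read_gwas_table <- function(path, dialect = NULL, query = NULL,
                            trait_id = NULL) {
  dt <- data.table::fread(path)
  nm <- names(dt)
  canon <- c("snp", "chr", "pos", "beta", "se", "z", "p", "maf", "n", "s",
             "type")
  map <- stats::setNames(canon, canon)
  if (!is.null(dialect)) map[names(dialect)] <- dialect
  col <- function(k) if (map[[k]] %in% nm) dt[[map[[k]]]] else NULL
  if (is.null(col("snp"))) stop_format("missing required column: snp")
  has_bse <- !is.null(col("beta")) && !is.null(col("se"))
  if (!has_bse && is.null(col("z")))
    stop_format("need either columns (beta, se) or z")
  req <- if (has_bse) c("snp", "beta", "se") else c("snp", "z")
  keep <- rowSums(is.na(dt[, map[req], with = FALSE])) == 0L
  if (any(!keep)) {
    message(sum(!keep), " row(s) dropped for missing required fields")
    dt <- dt[keep]
  }
  snp <- as.character(col("snp"))
  qidx <- if (is.null(query)) NA_integer_ else match(query, snp)
  if (!is.null(query) && is.na(qidx))
    stop_validation("query variant ", query, " not present in ", path)
  type <- col("type")
  trait_type <- if (!is.null(type) && any(type %in% c("quant", "quantitative")))
    "quant" else "cc"
  region_summary(
    snp_ids = snp, chr = col("chr"), pos = col("pos"),
    beta = col("beta"), se = col("se"), z = col("z"), pval = col("p"),
    maf = col("maf"),
    n = if (!is.null(col("n"))) col("n")[1L] else NULL,
    s = if (!is.null(col("s"))) col("s")[1L] else NULL,
    trait_type = trait_type, query_index = qidx,
    trait_id = trait_id %||% sub("\\.(tsv|csv|txt)(\\.gz)?$", "",
                                 basename(path)))
}

#' Write a region summary as a tab-delimited table
#'
#' Inverse of [read_gwas_table()]: numeric fields survive a write/read
#' round-trip at full precision.
#'
#' @param region a [region_summary()].
#' @param path output path (`.gz` suffix compresses).
#' @export
write_gwas_table <- function(region, path) {
  Q <- n_snps(region)
  dt <- data.table::data.table(
    snp = region$snp_ids, chr = region$chr, pos = region$pos,
    beta = region$beta %||% rep(NA_real_, Q),
    se = region$se %||% rep(NA_real_, Q),
    z = region$z, p = region$pval,
    maf = region$maf %||% rep(NA_real_, Q),
    n = rep(region$n %||% NA_real_, Q),
    s = rep(region$s %||% NA_real_, Q),
    type = rep(region$trait_type, Q))
  # %.17g so doubles round-trip bit-exactly through the text format
  num <- names(dt)[vapply(dt, is.double, TRUE)]
  for (cn in num) data.table::set(dt, j = cn,
                                  value = sprintf("%.17g", dt[[cn]]))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read an LD matrix with a sidecar id list
#'
#' @param path whitespace-delimited square matrix file.
#' @param ids_path one id per line, in matrix order; defaults to
#'   `paste0(path, ".ids")`.
#' @inheritParams ld_matrix
#' @export
read_ld_matrix <- function(path, ids_path = paste0(path, ".ids"),
                           regularize = TRUE, eps = 1e-4) {
  r <- as.matrix(data.table::fread(path, header = FALSE))
  ids <- readLines(ids_path)
  ld_matrix(unname(r), ids, regularize = regularize, eps = eps)
}

#' Write an LD matrix and its sidecar id list
#' @param ld an [ld_matrix()].
#' @inheritParams read_ld_matrix
#' @export
write_ld_matrix <- function(ld, path, ids_path = paste0(path, ".ids")) {
  m <- unclass(ld)
  lines <- apply(m, 1L, function(row)
    paste(sprintf("%.17g", row), collapse = "\t"))
  writeLines(lines, path)
  writeLines(rownames(ld), ids_path)
  invisible(path)
}

swap_alleles <- function(ids) {
  parts <- strsplit(ids, "_", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) == 4L) paste(p[1L], p[2L], p[4L], p[3L], sep = "_")
    else paste(p, collapse = "_")
  }, "")
}

#' Align a region summary to an LD matrix
#'
#' Restricts both objects to their shared variants, reorders them
#' identically, and harmonizes effect alleles: a region variant whose id
#' matches the LD panel only with ref/alt swapped has its `z` and `beta`
#' signs flipped and adopts the panel id. The query variant must survive
#' the intersection.
#'
#' @param region a [region_summary()].
#' @param ld an [ld_matrix()].
#' @return list with elements `region` and `ld`, aligned.
#' @export
align_to_ld <- function(region, ld) {
  panel <- rownames(ld)
  direct <- match(region$snp_ids, panel)
  flipped <- match(swap_alleles(region$snp_ids), panel)
  flipped[!is.na(direct)] <- NA  # direct match wins
  use <- !is.na(direct) | !is.na(flipped)
  if (!any(use)) stop_validation("no shared variants between region and LD")
  if (!is.na(region$query_index) && !use[region$query_index])
    stop_validation("query variant ", region$snp_ids[region$query_index],
                    " not present in the LD panel: region unusable")
  flip <- !is.na(flipped)
  panel_idx <- ifelse(flip, flipped, direct)
  # order by panel position so both objects share one ordering
  ord <- order(panel_idx[use])
  sel <- which(use)[ord]
  sgn <- ifelse(flip[sel], -1, 1)
  r2 <- region
  for (f in c("snp_ids", "chr", "pos", "beta", "se", "z", "pval", "maf"))
    if (!is.null(r2[[f]])) r2[[f]] <- r2[[f]][sel]
  r2$z <- r2$z * sgn
  if (!is.null(r2$beta)) r2$beta <- r2$beta * sgn
  r2$snp_ids <- panel[panel_idx[sel]]
  if (!is.na(region$query_index))
    r2$query_index <- match(region$query_index, sel)
  ids <- panel[panel_idx[sel]]
  ld2 <- ld_matrix(unclass(ld)[ids, ids, drop = FALSE], ids,
                   regularize = FALSE)
  list(region = r2, ld = ld2)
}

#' Quality-control filters for a region
#'
#' Flags the region as non-testable when the approximate allele count of the
#' query variant among cases, `2 * n * s * maf`, does not exceed
#' `min_case_ac`, and removes variants falling inside the HLA interval on
#' chromosome 6.
#'
#' @param region a [region_summary()].
#' @param min_case_ac minimum case allele count (exclusive); default 25.
#' @param hla_interval numeric length-2, HLA exclusion window on chr6 in
#'   base pairs; default `c(20e6, 40e6)`.
#' @return the filtered region, with attribute `testable` (logical).
#' @export
qc_filter <- function(region, min_case_ac = 25, hla_interval = c(20e6, 40e6)) {
  in_hla <- !is.na(region$chr) & region$chr %in% c("6", "chr6") &
    !is.na(region$pos) &
    region$pos >= hla_interval[1L] & region$pos <= hla_interval[2L]
  testable <- TRUE
  if (!is.na(region$query_index)) {
    if (in_hla[region$query_index]) testable <- FALSE
    if (region$trait_type == "cc" && !is.null(region$maf) &&
        !is.null(region$n) && !is.null(region$s)) {
      ac <- 2 * region$n * region$s * region$maf[region$query_index]
      if (ac <= min_case_ac) testable <- FALSE
    }
  }
  if (any(in_hla)) {
    qid <- if (!is.na(region$query_index))
      region$snp_ids[region$query_index] else NA_character_
    keep <- which(!in_hla)
    for (f in c("snp_ids", "chr", "pos", "beta", "se", "z", "pval", "maf"))
      if (!is.null(region[[f]])) region[[f]] <- region[[f]][keep]
    region$query_index <- if (is.na(qid)) NA_integer_
      else match(qid, region$snp_ids) %||% NA_integer_
  }
  attr(region, "testable") <- testable
  region
}

#' Read a covariate table
#'
#' Two columns: `trait_id` and `rg`, the genetic correlation between the
#' primary trait and each query trait, in \[-1, 1\].
#'
#' @param path delimited file with header.
#' @return data.table with columns `trait_id`, `rg`.
#' @export
read_covariate_table <- function(path) {
  dt <- data.table::fread(path)
  if (!all(c("trait_id", "rg") %in% names(dt)))
    stop_format("covariate table needs columns trait_id, rg")
  if (any(abs(dt$rg) > 1, na.rm = TRUE))
    stop_validation("rg must lie in [-1, 1]")
  dt[, c("trait_id", "rg"), with = FALSE]
}
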