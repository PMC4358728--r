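#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF 4.x file with `vcfR`, keeps biallelic SNV records only, and
#' maps GT fields to genotype codes (`0/0 -> 0`, `0/1` or `1/0 -> 1`,
#' `1/1 -> 2`, `./.` -> `-1`; phased separators are accepted). Records with
#' a non-SNV REF/ALT (indels, multiallelics, symbolic alleles) are skipped
#' and counted. Genotype likelihoods are recovered from a GL field
#' (log10-scaled likelihoods) or a PL field (phred-scaled) when present.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param keep_likelihoods Parse GL/PL into a `genotype_likelihoods` object
#'   when available.
#' @return List with elements `genotypes` (a `genotype_matrix` carrying an
#'   `n_skipped` attribute), and `likelihoods` (a `genotype_likelihoods` or
#'   `NULL`).
#' @export
read_vcf <- function(path, keep_likelihoods = TRUE) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  check_vcf_lines(path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("failed to parse VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  nt <- c("A", "C", "G", "T")
  snv <- fix[, "REF"] %in% nt & fix[, "ALT"] %in% nt
  n_skipped <- sum(!snv)
  if (n_skipped > 0)
    message(n_skipped, " non-SNV or multiallelic record(s) skipped")
  if (!any(snv)) stop("no biallelic SNV records in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")[snv, , drop = FALSE]
  samples <- colnames(gt)
  code <- matrix(-1L, nrow(gt), ncol(gt))
  gtn <- gsub("|", "/", gt, fixed = TRUE)
  code[gtn %in% "0/0"] <- 0L
  code[gtn %in% c("0/1", "1/0")] <- 1L
  code[gtn %in% "1/1"] <- 2L
  sites <- data.frame(chrom = fix[snv, "CHROM"],
                      pos = as.integer(fix[snv, "POS"]),
                      ref = fix[snv, "REF"], alt = fix[snv, "ALT"],
                      id = fix[snv, "ID"], stringsAsFactors = FALSE)
  gm <- genotype_matrix(t(code), sites, samples)
  attr(gm, "n_skipped") <- n_skipped
  gl <- NULL
  if (keep_likelihoods) {
    fmt <- vcf@gt[snv, 1L]
    if (any(grepl("GL", fmt, fixed = TRUE))) {
      raw <- vcfR::extract.gt(vcf, element = "GL")[snv, , drop = FALSE]
      gl <- parse_likelihood_field(raw, sites, samples,
                                   function(x) 10^x)
    } else if (any(grepl("PL", fmt, fixed = TRUE))) {
      raw <- vcfR::extract.gt(vcf, element = "PL")[snv, , drop = FALSE]
      gl <- parse_likelihood_field(raw, sites, samples,
                                   function(x) 10^(-x / 10))
    }
  }
  list(genotypes = gm, likelihoods = gl)
}

# Cheap structural pass so malformed bodies are reported with a line number
# (vcfR's own errors do not carry one).
check_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#"))
  for (i in body) {
    nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1L]])
    if (nf < 8L)
      stop("malformed VCF record at line ", i, " of ", path,
           " (", nf, " tab-separated fields)", call. = FALSE)
  }
  invisible(TRUE)
}

parse_likelihood_field <- function(raw, sites, samples, transform) {
  split <- strsplit(as.vector(raw), ",", fixed = TRUE)
  ok <- lengths(split) == 3L
  vals <- matrix(NA_real_, length(split), 3L)
  vals[ok, ] <- matrix(as.numeric(unlist(split[ok])), ncol = 3L,
                       byrow = TRUE)
  lik <- array(NA_real_, c(length(samples), nrow(sites), 3L))
  for (g in 1:3) {
    m <- matrix(vals[, g], nrow(sites), length(samples))
    lik[, , g] <- t(transform(m))
  }
  lik[!is.finite(lik)] <- 0
  genotype_likelihoods(lik, sites, samples)
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits a minimal plain-text VCF with GT calls and, when likelihoods are
#' supplied, a GL field (log10 likelihoods).
#'
#' @param gm A `genotype_matrix`.
#' @param path Output file path.
#' @param gl Optional `genotype_likelihoods` matching `gm`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, gl = NULL) {
  gt_str <- c("0/0", "0/1", "1/1")
  calls <- gm$calls
  body <- matrix("./.", nrow = n_sites(gm), ncol = n_samples(gm))
  for (g in 0:2) body[t(calls == g)] <- gt_str[g + 1L]
  fmt <- "GT"
  if (!is.null(gl)) {
    stopifnot(inherits(gl, "genotype_likelihoods"))
    l <- pmax(gl$lik, 1e-300)
    glstr <- matrix(
      paste(formatC(log10(l[, , 1L]), format = "g", digits = 6),
            formatC(log10(l[, , 2L]), format = "g", digits = 6),
            formatC(log10(l[, , 3L]), format = "g", digits = 6), sep = ","),
      n_samples(gm), n_sites(gm))
    body <- matrix(paste(body, t(glstr), sep = ":"),
                   n_sites(gm), n_samples(gm))
    fmt <- "GT:GL"
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=divsweep",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (!is.null(gl))
      '##FORMAT=<ID=GL,Number=G,Type=Float,Description="Log10 genotype likelihoods">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )
  id <- ifelse(is.na(gm$sites$id), ".", gm$sites$id)
  recs <- paste(gm$sites$chrom, gm$sites$pos, id, gm$sites$ref,
                gm$sites$alt, ".", "PASS", ".", fmt,
                apply(body, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read a population manifest (sample, label) TSV
#' @param path Two-column tab-separated file with header `sample	label`.
#' @return A `population_manifest`.
#' @export
read_manifest <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("sample", "label") %in% names(d)))
    stop("manifest must have columns 'sample' and 'label'")
  population_manifest(d$sample, d$label)
}

#' Write a population manifest TSV
#' @param manifest A `population_manifest`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Check that a manifest covers a genotype matrix
#'
#' @param gm A `genotype_matrix`.
#' @param manifest A `population_manifest`.
#' @param require_three Require all of wild, landrace and elite to be
#'   non-empty (needed for three-population analyses).
#' @return `TRUE`, invisibly; errors otherwise.
#' @export
validate_manifest <- function(gm, manifest, require_three = FALSE) {
  missing <- setdiff(gm$samples, manifest$sample)
  if (length(missing))
    stop("samples not in manifest: ", paste(missing, collapse = ", "))
  if (require_three) {
    for (lab in c("wild", "landrace", "elite")) {
      if (!any(manifest$sample[manifest$label == lab] %in% gm$samples))
        stop("population '", lab, "' is empty")
    }
  }
  invisible(TRUE)
}
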