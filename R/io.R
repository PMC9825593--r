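#' Read a genotype matrix from VCF or dosage TSV
#'
#' VCF genotypes (GT field) are collapsed to alternate-allele dosages
#' (0/1/2, missing = NA); multi-allelic records are skipped and counted.
#' The dosage TSV dialect has a header row
#' `variant_id chrom pos <sample1> <sample2> ...`, tab-separated, with
#' entries 0/1/2 and `.` for missing.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"vcf"` or `"dosage_tsv"`.
#' @return List of class `dosage_table`: `variants` (data.frame `id`,
#'   `chrom`, `pos`, `ref`, `alt`), `geno` (integer matrix, individuals x
#'   variants), `n_multiallelic_skipped`.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage_tsv"
  if (format == "vcf") .read_vcf(path) else .read_dosage_tsv(path)
}

.check_sorted <- function(variants) {
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p, strictly = FALSE))
      stop("positions not sorted within chromosome ", ch)
  }
}

.read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  n_skip <- sum(multi)
  if (n_skip) {
    message(n_skip, " multi-allelic record(s) skipped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  # count alternate alleles in GT strings like 0/1, 1|1, .
  dos <- apply(gt, 2, function(col) {
    alt <- vapply(strsplit(ifelse(is.na(col), "", col), "[/|]"), function(al)
      if (!length(al) || any(al == ".")) NA_integer_
      else sum(al == "1"), NA_integer_)
    alt
  })
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1L,
                                       dimnames = list(NULL, names(dos)))
  variants <- data.frame(
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, "_", fix$POS), fix$ID),
    chrom = fix$CHROM, pos = as.numeric(fix$POS),
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  .check_sorted(variants)
  geno <- t(dos)
  colnames(geno) <- variants$id
  structure(list(variants = variants, geno = geno,
                 n_multiallelic_skipped = n_skip),
            class = "dosage_table")
}

.read_dosage_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  need <- c("variant_id", "chrom", "pos")
  if (!all(need %in% names(df)[1:3]))
    stop("dosage TSV must start with columns: ", paste(need, collapse = ", "))
  samples <- names(df)[-(1:3)]
  if (!length(samples)) stop("dosage TSV has no sample columns")
  mat <- as.matrix(df[, samples, drop = FALSE])
  bad <- matrix(!(mat %in% c("0", "1", "2", ".")), nrow = nrow(mat))
  if (any(bad)) {
    row <- which(apply(bad, 1, any))[1]
    stop("malformed dosage at data line ", row, " of ", path)
  }
  geno <- matrix(suppressWarnings(as.integer(ifelse(mat == ".", NA, mat))),
                 nrow = nrow(mat))
  variants <- data.frame(id = df$variant_id, chrom = df$chrom,
                         pos = as.numeric(df$pos),
                         ref = NA_character_, alt = NA_character_,
                         stringsAsFactors = FALSE)
  if (anyNA(variants$pos)) stop("non-numeric position in dosage TSV")
  if (anyDuplicated(variants$id)) stop("duplicate variant ids in dosage TSV")
  .check_sorted(variants)
  geno <- t(geno)
  rownames(geno) <- samples
  colnames(geno) <- variants$id
  structure(list(variants = variants, geno = geno,
                 n_multiallelic_skipped = 0L),
            class = "dosage_table")
}

#' Write a genotype matrix as dosage TSV
#'
#' @param geno Integer dosage matrix, individuals x variants (NA = missing).
#' @param variants data.frame with `id`, `chrom`, `pos` matching the columns
#'   of `geno`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(geno, variants, path) {
  stopifnot(ncol(geno) == nrow(variants))
  mat <- t(geno)
  mat[is.na(mat)] <- "."
  df <- data.frame(variant_id = variants$id, chrom = variants$chrom,
                   pos = variants$pos, mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[-(1:3)] <- rownames(geno)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a VCFv4.2 file with GT-only genotypes (unphased; `./.` for
#' missing). Reference and alternate alleles default to A/B placeholders
#' when the variant table does not carry them.
#'
#' @inheritParams write_dosage_tsv
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, variants, path) {
  stopifnot(ncol(geno) == nrow(variants))
  ref <- if ("ref" %in% names(variants) && !anyNA(variants$ref))
    variants$ref else rep("A", nrow(variants))
  alt <- if ("alt" %in% names(variants) && !anyNA(variants$alt))
    variants$alt else rep("B", nrow(variants))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- t(apply(geno, 1, function(row)
    ifelse(is.na(row), "./.", gt_code[as.character(row)])))
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(geno)), collapse = "\t"))
  body <- vapply(seq_len(nrow(variants)), function(i)
    paste(c(variants$chrom[i], format(variants$pos[i], scientific = FALSE),
            variants$id[i], ref[i], alt[i], ".", "PASS", ".", "GT",
            gt[, i]), collapse = "\t"), "")
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a genetic map in HapMap format
#'
#' Four whitespace-separated columns: chromosome, position (bp), rate
#' (cM/Mb, unused), cumulative cM. A header line is tolerated. Cumulative
#' values must be non-decreasing within each chromosome (the offending row
#' is named otherwise); a nonzero first value is treated as an offset and
#' shifted to zero.
#'
#' @param path File path.
#' @return Named list of [genetic_map()] objects, one per chromosome.
#' @export
read_genetic_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(trimws(first), "\\s+")[[1]][2])))
  df <- utils::read.table(path, header = has_header,
                          col.names = c("chrom", "pos", "rate", "cM"),
                          colClasses = c("character", "numeric", "numeric",
                                         "numeric"))
  maps <- lapply(split(df, factor(df$chrom, levels = unique(df$chrom))),
                 function(d) {
    bad <- which(diff(d$cM) < 0)
    if (length(bad))
      stop("cumulative cM decreases at row ", bad[1] + 1L,
           " of chromosome ", d$chrom[1])
    genetic_map(d$chrom[1], d$pos, d$cM - d$cM[1])
  })
  maps
}

#' Write genetic maps in HapMap format
#'
#' @param maps A [genetic_map()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(maps, path) {
  if (inherits(maps, "genetic_map")) maps <- list(maps)
  rows <- do.call(rbind, lapply(maps, function(m) {
    rate <- c(diff(m$cum_cM) / diff(m$pos) * 1e6, 0)
    data.frame(chrom = m$chrom, pos = m$pos, rate = rate, cM = m$cum_cM)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = c("chr", "position", "rate.cM.Mb.",
                                   "cM.cumulative."))
  invisible(path)
}

#' Write a break catalog as BED
#'
#' Columns: chrom, start, end (0-based half-open marker-gap bracket), name
#' (pair id), score (Z), direction. Readable back with
#' [read_breaks_bed()].
#'
#' @param catalog A [break_catalog()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_breaks_bed <- function(catalog, path) {
  stopifnot(inherits(catalog, "break_catalog"))
  df <- data.frame(
    chrom = catalog$chrom,
    start = if ("start" %in% names(catalog)) catalog$start
            else floor(catalog$mid_bp),
    end = if ("end" %in% names(catalog)) catalog$end
          else floor(catalog$mid_bp) + 1,
    name = if ("pair" %in% names(catalog)) catalog$pair else ".",
    score = if ("Z" %in% names(catalog)) catalog$Z else 0,
    direction = if ("direction" %in% names(catalog)) catalog$direction
                else ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a break catalog from BED
#'
#' @param path BED file written by [write_breaks_bed()].
#' @param n_pairs Number of pairs behind the catalog.
#' @return A [break_catalog()].
#' @export
read_breaks_bed <- function(path, n_pairs) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "pair",
                                        "Z", "direction"),
                          colClasses = c("character", "numeric", "numeric",
                                         "character", "numeric", "character"))
  df$mid_bp <- (df$start + df$end + 1) / 2
  break_catalog(df, n_pairs)
}

#' Write the crossover truth of a simulated cohort as TSV
#'
#' @param cohort A `sib_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_crossovers_tsv <- function(cohort, path) {
  utils::write.table(true_crossovers(cohort), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ground-truth region segments of one pair as BED
#'
#' One line per constant-type segment: chrom, start, end (0-based
#' half-open), name = `type<k>`.
#'
#' @param cohort A `sib_cohort`.
#' @param pair Pair index.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_segments_bed <- function(cohort, pair, path) {
  rows <- do.call(rbind, lapply(names(cohort$maps), function(ch) {
    seg <- true_region_segments(cohort, pair, ch)
    data.frame(chrom = ch, start = seg$start, end = seg$end,
               name = paste0("type", seg$type))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
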