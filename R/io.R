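# io_core: containers and readers/writers for genotype matrices, parental
# allele-frequency panels, per-individual metadata and perception bands.

#' Construct a genotype matrix
#'
#' Counts refer to the panel's designated reference allele per marker and
#' are bounded by ploidy 2; `NA` encodes missing genotypes.
#'
#' @param counts integer matrix, individuals in rows, markers in columns;
#'   entries in \{0, 1, 2\} or `NA`
#' @param sample_ids,marker_ids unique identifiers for rows / columns
#' @return an object of class `genotype_matrix` (a validated integer matrix
#'   with dimnames)
#' @export
genotype_matrix <- function(counts, sample_ids = rownames(counts),
                            marker_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids) || is.null(marker_ids))
    stop_config("genotype_matrix needs sample and marker ids")
  if (anyDuplicated(sample_ids)) stop_config("duplicate sample ids")
  if (anyDuplicated(marker_ids)) stop_config("duplicate marker ids")
  storage.mode(counts) <- "integer"
  bad <- !is.na(counts) & (counts < 0L | counts > 2L)
  if (any(bad))
    stop_config("genotype counts outside {0,1,2}: first offender row %d col %d",
                which(bad, arr.ind = TRUE)[1, 1], which(bad, arr.ind = TRUE)[1, 2])
  dimnames(counts) <- list(as.character(sample_ids), as.character(marker_ids))
  structure(counts, class = c("genotype_matrix", "matrix", "array"))
}

#' Construct a parental allele-frequency panel
#'
#' @param freqs numeric matrix, markers in rows, ancestral populations in
#'   columns, entries in \[0, 1\]
#' @param marker_ids marker identifiers (rows)
#' @param population_labels population labels (columns), default AFR/EUR/NAM
#' @param reference_allele optional character vector of reference alleles per
#'   marker (defaults to "A"; the designated counted allele)
#' @param alt_allele optional character vector of the other allele (default "G")
#' @return an object of class `parental_panel`
#' @export
parental_panel <- function(freqs, marker_ids = rownames(freqs),
                           population_labels = colnames(freqs),
                           reference_allele = NULL, alt_allele = NULL) {
  freqs <- as.matrix(freqs)
  if (is.null(population_labels))
    population_labels <- c("AFR", "EUR", "NAM")[seq_len(ncol(freqs))]
  if (is.null(marker_ids)) marker_ids <- paste0("rs", seq_len(nrow(freqs)))
  if (anyDuplicated(marker_ids)) stop_config("duplicate marker ids in panel")
  if (any(freqs < 0 | freqs > 1, na.rm = TRUE))
    stop_config("panel frequencies outside [0,1]")
  dimnames(freqs) <- list(as.character(marker_ids), population_labels)
  if (is.null(reference_allele)) reference_allele <- rep("A", nrow(freqs))
  if (is.null(alt_allele)) alt_allele <- rep("G", nrow(freqs))
  structure(list(freqs = freqs,
                 marker_ids = as.character(marker_ids),
                 population_labels = population_labels,
                 reference_allele = reference_allele,
                 alt_allele = alt_allele),
            class = "parental_panel")
}

#' @export
print.parental_panel <- function(x, ...) {
  cat(sprintf("parental_panel: %d markers x %d populations (%s)\n",
              nrow(x$freqs), ncol(x$freqs),
              paste(x$population_labels, collapse = "/")))
  invisible(x)
}

#' Read genotypes from VCF or TSV
#'
#' For VCF input the ALT allele is taken as the counted (reference-panel)
#' allele, so GT `0/0`, `0/1`, `1/1` become counts 0, 1, 2. Unparseable or
#' missing genotypes (`./.`) become `NA`. Non-biallelic records and ploidy
#' other than 2 are format errors naming the offending record.
#'
#' @param path file path
#' @param format `"vcf"` or `"tsv"`; default guessed from the extension
#' @return a [genotype_matrix()]
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  if (!file.exists(path)) stop_config("file not found: %s", path)
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    stop_config("non-biallelic VCF record: %s", ids[which(multi)[1]])
  gt <- vcfR::extract.gt(v, element = "GT")
  # rows = markers, cols = samples
  core <- sub(":.*$", "", gt)
  alleles <- strsplit(gsub("\\|", "/", core), "/", fixed = FALSE)
  nall <- lengths(alleles)
  ok <- is.na(core) | core %in% c(".", "./.", ".|.") | nall == 2L
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = FALSE)[1]
    stop_config("VCF genotype with ploidy != 2 at record %s",
                ids[(bad - 1L) %% nrow(core) + 1L])
  }
  counts <- vapply(alleles, function(a) {
    if (length(a) != 2L || any(a == ".")) return(NA_integer_)
    suppressWarnings(s <- sum(as.integer(a)))
    if (is.na(s) || s > 2L) NA_integer_ else s
  }, integer(1))
  counts <- matrix(counts, nrow = nrow(core), dimnames = dimnames(core))
  admix_log("read %d markers x %d samples from %s", nrow(counts),
            ncol(counts), path)
  genotype_matrix(t(counts), sample_ids = colnames(counts), marker_ids = ids)
}

read_genotypes_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  genotype_matrix(m, sample_ids = ids, marker_ids = colnames(df)[-1])
}

#' Write genotypes as a TSV allele-count matrix
#'
#' @param g a [genotype_matrix()]
#' @param path output path
#' @export
write_genotypes_tsv <- function(g, path) {
  df <- data.frame(sample_id = rownames(g), as.data.frame(unclass(g)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write genotypes as a minimal biallelic VCF 4.2
#'
#' The counted allele is emitted as ALT (REF/ALT taken from the panel when
#' supplied), so a round-trip through [read_genotypes()] is lossless.
#'
#' @param g a [genotype_matrix()]
#' @param path output path
#' @param panel optional [parental_panel()] supplying REF/ALT alleles
#' @export
write_genotypes_vcf <- function(g, path, panel = NULL) {
  m <- ncol(g)
  ref <- if (!is.null(panel)) panel$alt_allele[match(colnames(g), panel$marker_ids)] else rep("T", m)
  alt <- if (!is.null(panel)) panel$reference_allele[match(colnames(g), panel$marker_ids)] else rep("A", m)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(g)), collapse = "\t"))
  body <- vapply(seq_len(m), function(j) {
    gts <- ifelse(is.na(g[, j]), "./.", gt_code[as.character(g[, j])])
    paste(c("1", j, colnames(g)[j], ref[j], alt[j], ".", "PASS", ".",
            "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Write / read a parental frequency panel as CSV
#' @param panel a [parental_panel()]
#' @param path file path
#' @export
write_panel_csv <- function(panel, path) {
  df <- data.frame(marker_id = panel$marker_ids,
                   reference_allele = panel$reference_allele,
                   alt_allele = panel$alt_allele,
                   as.data.frame(panel$freqs), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  pops <- setdiff(names(df), c("marker_id", "reference_allele", "alt_allele"))
  parental_panel(as.matrix(df[, pops]), marker_ids = df$marker_id,
                 population_labels = pops,
                 reference_allele = df$reference_allele,
                 alt_allele = df$alt_allele)
}

#' Align a genotype matrix and a frequency panel on shared markers
#'
#' Both objects are restricted to the intersection of marker ids, in panel
#' order. Where the two sources designate opposite alleles the genotype
#' counts are flipped (`g -> 2 - g`); the likelihood downstream is invariant
#' under the simultaneous flip `g -> 2 - g`, `f -> 1 - f`.
#'
#' @param genotypes a [genotype_matrix()]
#' @param panel a [parental_panel()]
#' @param genotype_counted_allele optional character vector, one per genotype
#'   column, naming the allele the counts refer to; markers whose entry
#'   matches the panel's `alt_allele` are flipped
#' @return list with elements `genotypes` and `panel`, aligned
#' @export
align_panel <- function(genotypes, panel, genotype_counted_allele = NULL) {
  shared <- intersect(panel$marker_ids, colnames(genotypes))
  if (length(shared) == 0L)
    stop_config("no shared markers between genotypes and panel")
  g <- genotypes[, shared, drop = FALSE]
  keep <- match(shared, panel$marker_ids)
  p <- parental_panel(panel$freqs[keep, , drop = FALSE],
                      marker_ids = shared,
                      population_labels = panel$population_labels,
                      reference_allele = panel$reference_allele[keep],
                      alt_allele = panel$alt_allele[keep])
  if (!is.null(genotype_counted_allele)) {
    ga <- genotype_counted_allele[match(shared, colnames(genotypes))]
    flip <- !is.na(ga) & ga == p$alt_allele
    if (any(flip)) {
      g[, flip] <- 2L - g[, flip]
      admix_log("flipped %d markers to the panel's reference allele", sum(flip))
    }
  }
  admix_log("aligned %d shared markers (%d dropped from genotypes, %d from panel)",
            length(shared), ncol(genotypes) - length(shared),
            nrow(panel$freqs) - length(shared))
  list(genotypes = genotype_matrix(g), panel = p)
}

#' Read / write per-individual metadata and perception tables
#'
#' Thin CSV wrappers with factor/level validation for the columns the
#' pipeline uses (ordinal trait codes, coordinates, perception bands).
#'
#' @param path file path
#' @return data.frame
#' @export
read_pheno_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("birth_lat", "birth_lon") %in% names(df))) {
    if (any(abs(df$birth_lat) > 90, na.rm = TRUE) ||
        any(abs(df$birth_lon) > 180, na.rm = TRUE))
      stop_config("coordinates out of range in %s", path)
  }
  if ("education" %in% names(df) &&
      !all(df$education %in% c(1:3, NA)))
    stop_config("education codes outside 1-3 in %s", path)
  df
}

#' @rdname read_pheno_csv
#' @param bands data.frame with columns sample_id and per-continent band
#'   columns (values 1-5)
#' @export
read_perception_csv <- function(path) {
  bands <- utils::read.csv(path, stringsAsFactors = FALSE)
  bc <- setdiff(names(bands), "sample_id")
  for (cn in bc)
    if (!all(bands[[cn]] %in% c(1:5, NA)))
      stop_config("perception band outside 1-5 in column %s", cn)
  bands
}
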