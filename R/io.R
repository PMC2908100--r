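# Tab-separated genotype/phenotype tables: the package's single on-disk
# dialect. Mandatory header with columns sample_id, genotype, phenotype;
# genotype as AAA/AAa/Aaa/aaa or A-copy counts 3/2/1/0; an optional
# configuration column (M/P) carries the simulator's latent truth.

#' Read a genotype/phenotype table
#'
#' @param path path to a tab-separated file with header columns
#'   `sample_id`, `genotype`, `phenotype` (and optionally
#'   `configuration`).
#' @return A [phenotype_sample()]; if a configuration column is present
#'   it is attached as attribute `"configuration"` (integer, 1 =
#'   maternal duplication).
#' @export
read_genopheno <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("sample_id", "genotype", "phenotype")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(tab) == 0) stop("table has a header but no data rows")
  pheno <- suppressWarnings(as.numeric(tab$phenotype))
  if (anyNA(pheno)) {
    bad <- which(is.na(pheno))[1]
    stop("phenotype not a finite decimal at data row ", bad, ": '",
         tab$phenotype[bad], "'")
  }
  if (anyDuplicated(tab$sample_id))
    stop("duplicated sample_id: ",
         tab$sample_id[anyDuplicated(tab$sample_id)])
  # genotype tokens from disk are always textual: digits mean A-copy
  # counts, never class indices
  out <- phenotype_sample(as.character(tab$genotype), pheno, tab$sample_id)
  if ("configuration" %in% names(tab)) {
    j <- match(tab$configuration, CONFIG_LABELS)
    if (anyNA(j))
      stop("configuration column must contain only M or P (row ",
           which(is.na(j))[1], ")")
    attr(out, "configuration") <- j
  }
  counts <- tabulate(out$genotype, 4)
  message(sprintf("read %d subjects (AAA=%d, AAa=%d, Aaa=%d, aaa=%d)",
                  nrow(out), counts[1], counts[2], counts[3], counts[4]))
  out
}

#' Write a genotype/phenotype table
#'
#' @param x a [phenotype_sample()] or a `"simulated_sample"` (the latent
#'   configuration is then written as an extra column).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genopheno <- function(x, path) {
  config <- NULL
  if (inherits(x, "simulated_sample")) {
    config <- x$latent
    x <- x$sample
  } else if (!is.null(attr(x, "configuration"))) {
    config <- attr(x, "configuration")
  }
  stopifnot(inherits(x, "phenotype_sample"))
  tab <- data.frame(sample_id = x$sample_id,
                    genotype = GENOTYPE_LABELS[x$genotype],
                    phenotype = format(x$phenotype, digits = 15,
                                       trim = TRUE, scientific = FALSE))
  if (!is.null(config)) tab$configuration <- CONFIG_LABELS[config]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
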