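#' Read a VCF into a dosage matrix
#'
#' Uses only the GT field; "./." (or ".|.") becomes NA; multi-allelic
#' records are skipped with a count.
#'
#' @param path VCF file.
#' @return list: `genotypes` (individuals x loci dosage matrix), `loci`
#'   (snp, chrom, pos, contig), `skipped` (multi-allelic record count).
#' @export
readVcfGenotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  skipped <- sum(!bi)
  v <- v[bi, ]
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean == "0/0"] <- 0
  dos[clean %in% c("0/1", "1/0")] <- 1
  dos[clean == "1/1"] <- 2
  fix <- vcfR::getFIX(v)
  loci <- data.frame(snp = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                                  paste0(fix[, "CHROM"], ":", fix[, "POS"]),
                                  fix[, "ID"]),
                     chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     contig = NA_character_,
                     stringsAsFactors = FALSE)
  list(genotypes = t(dos), loci = loci, skipped = skipped)
}

#' Write a dosage matrix as a minimal VCF 4.2 (GT only)
#'
#' @param genotypes matrix individuals x loci of dosages 0/1/2/NA.
#' @param loci data.frame: snp, chrom, pos.
#' @param path output file.
#' @export
writeVcfGenotypes <- function(genotypes, loci, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(genotypes)),
                     collapse = "\t")), con)
  gtCode <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(genotypes))) {
    d <- genotypes[, j]
    gt <- ifelse(is.na(d), "./.", gtCode[d + 1])
    writeLines(paste(c(loci$chrom[j], loci$pos[j], loci$snp[j], "A", "G",
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a study bundle to a directory of plain-text files
#'
#' samples/traits/environment as CSV, genotypes as VCF and dosage TSV,
#' counts and gene table as TSV, ground truth as JSON.
#'
#' @param bundle a [StudyBundle-class].
#' @param dir output directory (created).
#' @export
writeStudyBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write.csv(studySamples(bundle), fp("samples.csv"), row.names = FALSE)
  write.csv(data.frame(id = rownames(traitMatrix(bundle)),
                       traitMatrix(bundle), check.names = FALSE),
            fp("traits.csv"), row.names = FALSE)
  write.csv(lakeEnvironment(bundle), fp("environment.csv"),
            row.names = FALSE)
  writeVcfGenotypes(genotypeMatrix(bundle), lociTable(bundle),
                    fp("genotypes.vcf"))
  utils::write.table(data.frame(id = rownames(genotypeMatrix(bundle)),
                                genotypeMatrix(bundle),
                                check.names = FALSE),
                     fp("dosages.tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(lociTable(bundle), fp("loci.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(gene = rownames(countMatrix(bundle)),
                                countMatrix(bundle), check.names = FALSE),
                     fp("counts.tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(geneTable(bundle), fp("genes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  tr <- studyTruth(bundle)
  tr <- lapply(tr, function(x)
    if (is.matrix(x)) list(rows = rownames(x), values = unname(as.data.frame(x)))
    else x)
  jsonlite::write_json(tr, fp("truth.json"), auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(dir)
}

#' Read a study bundle written by [writeStudyBundle()]
#'
#' @param dir the bundle directory.
#' @return A [StudyBundle-class] (the `truth` slot holds the decoded JSON,
#'   matrices flattened).
#' @export
readStudyBundle <- function(dir) {
  fp <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing bundle file: ", p)
    p
  }
  samples <- read.csv(fp("samples.csv"), stringsAsFactors = FALSE)
  tr <- read.csv(fp("traits.csv"), check.names = FALSE,
                 stringsAsFactors = FALSE)
  traits <- as.matrix(tr[, -1, drop = FALSE])
  rownames(traits) <- tr$id
  env <- read.csv(fp("environment.csv"), stringsAsFactors = FALSE)
  dos <- read.delim(fp("dosages.tsv"), check.names = FALSE,
                    stringsAsFactors = FALSE)
  genotypes <- as.matrix(dos[, -1, drop = FALSE])
  rownames(genotypes) <- dos$id
  loci <- read.delim(fp("loci.tsv"), stringsAsFactors = FALSE)
  ct <- read.delim(fp("counts.tsv"), check.names = FALSE,
                   stringsAsFactors = FALSE)
  counts <- as.matrix(ct[, -1, drop = FALSE])
  rownames(counts) <- ct$gene
  genes <- read.delim(fp("genes.tsv"), stringsAsFactors = FALSE)
  truth <- if (file.exists(file.path(dir, "truth.json")))
    jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  else list()
  new("StudyBundle", samples = samples, traits = traits,
      genotypes = genotypes, loci = loci, counts = counts, genes = genes,
      env = env, truth = as.list(truth))
}
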