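#' Read case-control genotype data
#'
#' Reads either whitespace-delimited PLINK text PED/MAP files or a plain TSV
#' genotype matrix into a [geno_matrix] plus a binary phenotype.
#'
#' For PED input, alleles at each SNP are counted so that the minor allele
#' *within the file* is the counted (dosage) allele; allele-frequency ties are
#' broken toward the lexicographically smaller allele symbol. `0` is the
#' missing-allele code; a genotype with any missing allele becomes code -1.
#' PED phenotype 1/2 is mapped to control/case 0/1.
#'
#' The TSV dialect has header `sample_id  phenotype  <snp_id>...` and cells in
#' \{0, 1, 2, NA\}.
#'
#' @param path file path. For `format = "ped_map"` give the `.ped` path (the
#'   `.map` is found by extension swap) or a prefix.
#' @param format `"ped_map"` or `"tsv"`.
#' @return list with elements `genotypes` ([geno_matrix]) and `phenotype`
#'   (integer 0/1 vector).
#' @export
read_genotypes <- function(path, format = c("tsv", "ped_map")) {
  format <- match.arg(format)
  if (format == "tsv") read_genotypes_tsv(path) else read_genotypes_ped(path)
}

read_genotypes_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 3L || names(df)[1] != "sample_id" || names(df)[2] != "phenotype")
    stop("TSV header must be 'sample_id<TAB>phenotype<TAB><snp ids>...'")
  snp_ids <- names(df)[-(1:2)]
  gm <- matrix(-1L, nrow(df), length(snp_ids))
  for (j in seq_along(snp_ids)) {
    v <- df[[j + 2L]]
    miss <- is.na(v) | v == "NA" | v == ""
    ok <- v[!miss] %in% c("0", "1", "2")
    if (!all(ok)) {
      stop(sprintf("parse error at line %d: invalid genotype '%s' for SNP %s",
                   which(!miss)[which(!ok)[1]] + 1L,
                   v[!miss][which(!ok)[1]], snp_ids[j]))
    }
    gm[!miss, j] <- as.integer(v[!miss])
  }
  phen <- suppressWarnings(as.integer(df$phenotype))
  if (any(is.na(phen)) || !all(phen %in% c(0L, 1L)))
    stop("phenotype column must contain 0/1")
  list(genotypes = geno_matrix(gm, snp_ids = snp_ids, sample_ids = df$sample_id),
       phenotype = phen)
}

ped_map_paths <- function(path) {
  if (grepl("\\.ped$", path)) {
    list(ped = path, map = sub("\\.ped$", ".map", path))
  } else if (grepl("\\.map$", path)) {
    list(ped = sub("\\.map$", ".ped", path), map = path)
  } else {
    list(ped = paste0(path, ".ped"), map = paste0(path, ".map"))
  }
}

read_genotypes_ped <- function(path) {
  pp <- ped_map_paths(path)
  if (!file.exists(pp$ped)) stop("file not found: ", pp$ped)
  if (!file.exists(pp$map)) stop("file not found: ", pp$map)
  map <- utils::read.table(pp$map, header = FALSE, colClasses = "character")
  if (ncol(map) < 4L) stop("MAP file must have 4 columns")
  snp_ids <- map[[2]]
  chrom <- map[[1]]
  pos <- as.numeric(map[[4]])
  p <- length(snp_ids)

  lines <- readLines(pp$ped)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  a1 <- matrix("0", n, p); a2 <- matrix("0", n, p)
  sample_ids <- character(n); phen <- integer(n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(tok) != 6L + 2L * p)
      stop(sprintf("parse error at line %d of %s: expected %d fields, found %d",
                   i, pp$ped, 6L + 2L * p, length(tok)))
    sample_ids[i] <- tok[2]
    ph <- tok[6]
    if (!ph %in% c("1", "2"))
      stop(sprintf("parse error at line %d: phenotype '%s' not in {1,2}", i, ph))
    phen[i] <- as.integer(ph) - 1L
    al <- tok[-(1:6)]
    a1[i, ] <- al[seq(1L, 2L * p, by = 2L)]
    a2[i, ] <- al[seq(2L, 2L * p, by = 2L)]
  }

  gm <- matrix(-1L, n, p)
  for (j in seq_len(p)) {
    al <- c(a1[, j], a2[, j])
    obs <- al[al != "0"]
    alleles <- sort(unique(obs))
    if (length(alleles) > 2L)
      stop("non-biallelic SNP rejected: ", snp_ids[j],
           " has alleles ", paste(alleles, collapse = "/"))
    if (length(obs) == 0L) next  # all missing, stays -1
    if (length(alleles) == 1L) {
      # monomorphic: the single observed allele is the major one, dosage 0
      miss <- a1[, j] == "0" | a2[, j] == "0"
      gm[!miss, j] <- 0L
      next
    }
    cnt <- c(sum(obs == alleles[1]), sum(obs == alleles[2]))
    # counted allele = minor within file; tie -> lexicographically smaller
    counted <- if (cnt[1] < cnt[2]) alleles[1]
               else if (cnt[2] < cnt[1]) alleles[2]
               else alleles[1]
    miss <- a1[, j] == "0" | a2[, j] == "0"
    dos <- (a1[, j] == counted) + (a2[, j] == counted)
    gm[!miss, j] <- as.integer(dos[!miss])
  }
  list(genotypes = geno_matrix(gm, snp_ids = snp_ids, sample_ids = sample_ids,
                               chrom = chrom, pos = pos),
       phenotype = phen)
}

#' Write genotype data
#'
#' Writes a [geno_matrix] plus phenotype in the same dialects that
#' [read_genotypes()] reads. For PED output the major allele is written as `A`
#' and the minor (counted) allele as `G`; missing genotypes become `0 0`.
#'
#' @param g a [geno_matrix].
#' @param phen binary phenotype vector (1 = case).
#' @param path output path (`.tsv`, or ped/map prefix).
#' @param format `"tsv"` or `"ped_map"`.
#' @return the path(s) written, invisibly.
#' @export
write_genotypes <- function(g, phen, path, format = c("tsv", "ped_map")) {
  format <- match.arg(format)
  phen <- check_phenotype(phen, g, require_both = FALSE)
  if (format == "tsv") {
    gm <- g$genotypes
    cells <- matrix(as.character(gm), nrow(gm), ncol(gm))
    cells[gm == -1L] <- "NA"
    df <- data.frame(sample_id = g$sample_ids, phenotype = phen,
                     check.names = FALSE, stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(cells, stringsAsFactors = FALSE))
    names(df) <- c("sample_id", "phenotype", g$snp_ids)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  pp <- ped_map_paths(path)
  p <- ncol(g$genotypes); n <- nrow(g$genotypes)
  chrom <- if (is.null(g$chrom)) rep("1", p) else g$chrom
  pos <- if (is.null(g$pos)) seq_len(p) else g$pos
  map <- data.frame(chrom, g$snp_ids, 0, pos)
  utils::write.table(map, pp$map, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  allele_strings <- c("A A", "A G", "G G")  # dosage 0,1,2 of minor allele G
  con <- file(pp$ped, "w")
  on.exit(close(con))
  for (i in seq_len(n)) {
    gi <- g$genotypes[i, ]
    al <- ifelse(gi == -1L, "0 0", allele_strings[gi + 1L])
    writeLines(paste(c(g$sample_ids[i], g$sample_ids[i], "0", "0", "0",
                       phen[i] + 1L, al), collapse = " "), con)
  }
  invisible(c(pp$ped, pp$map))
}
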