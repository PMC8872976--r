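# Minimal PLINK 1 bed/bim/fam support (SNP-major, no missing genotypes on
# write; missing genotypes on read become an error since the panel container
# requires complete dosages).

#' Write a genotype panel as PLINK bed/bim/fam
#'
#' @param panel a [genotype_panel][simulate_genotypes].
#' @param prefix path prefix; `.bed`, `.bim`, `.fam` are appended.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(panel, prefix) {
  stopifnot(inherits(panel, "genotype_panel"))
  d <- panel$dosages
  n <- nrow(d); m <- ncol(d)
  # dosage of a1: 2 -> 00, 1 -> 10, 0 -> 11 (PLINK bed codes, no missing)
  code <- matrix(c(3L, 2L, 0L)[d + 1L], n, m)
  pad <- (4L - n %% 4L) %% 4L
  if (pad) code <- rbind(code, matrix(0L, pad, m))
  crumbs <- matrix(code, nrow = 4L)
  bytes <- as.raw(crumbs[1, ] + 4L * crumbs[2, ] + 16L * crumbs[3, ] + 64L * crumbs[4, ])
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(bytes, con)
  bim <- data.frame(panel$map$chrom, panel$map$snp_id, 0, panel$map$bp,
                    panel$map$a1, panel$map$a2)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  iid <- rownames(d) %||% sprintf("id%05d", seq_len(n))
  fam <- data.frame(iid, iid, 0, 0, 0, -9)
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a PLINK bed/bim/fam fileset into a genotype panel
#'
#' Supports the SNP-major bed layout. Missing genotype codes are rejected
#' (the panel container requires complete dosages). The `freq` column is the
#' sample a1 allele frequency.
#'
#' @param prefix path prefix of the `.bed`/`.bim`/`.fam` trio.
#' @return A [genotype_panel][simulate_genotypes].
#' @export
read_plink <- function(prefix) {
  fam <- read.table(paste0(prefix, ".fam"), stringsAsFactors = FALSE)
  bim <- read.table(paste0(prefix, ".bim"), stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  bpf <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK bed file")
  bytes <- as.integer(readBin(con, "raw", bpf * m))
  if (length(bytes) != bpf * m) stop("bed file truncated")
  crumbs <- rbind(bytes %% 4L, (bytes %/% 4L) %% 4L,
                  (bytes %/% 16L) %% 4L, (bytes %/% 64L) %% 4L)
  g <- matrix(as.vector(crumbs), nrow = 4L * bpf)[seq_len(n), , drop = FALSE]
  if (any(g == 1L)) stop("missing genotypes are not supported")
  dosages <- matrix(c(2L, NA_integer_, 1L, 0L)[g + 1L], n, m)
  rownames(dosages) <- fam[[2]]
  colnames(dosages) <- bim[[2]]
  map <- data.frame(snp_id = bim[[2]], chrom = bim[[1]], bp = bim[[4]],
                    a1 = as.character(bim[[5]]), a2 = as.character(bim[[6]]),
                    freq = colMeans(dosages) / 2, ld_block = seq_len(m),
                    stringsAsFactors = FALSE)
  structure(list(dosages = dosages, map = map, ld_rho = 0, ld_block_size = 1L),
            class = "genotype_panel")
}
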