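#' Construct a genotype reference panel
#'
#' @param geno Individuals x SNPs allele-count matrix (0/1/2).
#' @param map Data frame with one row per SNP: `chr`, `snp` (id), `cM`
#'   (genetic position, non-decreasing within chromosome), `bp`.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(geno, map) {
  geno <- as.matrix(geno)
  stopifnot(all(geno %in% 0:2),
            all(c("chr", "snp", "cM", "bp") %in% names(map)),
            nrow(map) == ncol(geno))
  mono <- apply(geno, 2, function(g) length(unique(g)) == 1)
  if (any(mono))
    stop(sum(mono), " monomorphic SNP(s) in panel; filter before construction")
  for (ch in unique(map$chr)) {
    cm <- map$cM[map$chr == ch]
    if (is.unsorted(cm)) stop("cM positions must be non-decreasing within ", ch)
  }
  colnames(geno) <- map$snp
  structure(list(geno = geno, map = map, n_ind = nrow(geno)),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d individuals x %d SNPs on %d chromosome(s)\n",
              x$n_ind, nrow(x$map), length(unique(x$map$chr))))
  invisible(x)
}

#' Construct a SNP-by-category annotation matrix
#'
#' Column 1 must be the base category (all ones); further columns are binary
#' memberships and may overlap (pooled cell-type clusters share regions).
#'
#' @param m SNP x category 0/1 matrix with column names; or `NULL` to build a
#'   base-only matrix for `n_snp` SNPs.
#' @param snp SNP ids (row identity).
#' @param n_snp Number of SNPs when `m` is `NULL`.
#' @return Matrix of class `annot_matrix` with rownames = SNP ids.
#' @export
annot_matrix <- function(m = NULL, snp, n_snp = length(snp)) {
  if (is.null(m)) m <- matrix(1, n_snp, 1, dimnames = list(NULL, "base"))
  m <- as.matrix(m)
  if (is.null(colnames(m))) stop("annotation columns must be named")
  if (!all(m %in% c(0, 1))) stop("annotation matrix must be binary")
  if (!all(m[, 1] == 1)) stop("first column must be the all-ones base category")
  rownames(m) <- snp
  class(m) <- c("annot_matrix", class(m))
  m
}

#' Annotation membership of SNPs from a binary track
#'
#' @param track A [binary_track()].
#' @param map Data frame with `chr` and `bp` (1-based SNP positions).
#' @return 0/1 vector, one entry per SNP.
#' @export
snp_in_track <- function(track, map) {
  as.integer(scores_at(track, data.frame(chr = map$chr, bp = map$bp)) > 0)
}

#' Annotation-stratified LD scores
#'
#' For SNP j and category c, l(j, c) is the sum of bias-adjusted squared
#' correlations r2_adj = r2 - (1 - r2) / (n - 2) between j and every
#' category-c SNP within `window_cM` genetic distance (including j itself
#' when j is in c; the self term is exactly 1). The adjustment removes the
#' finite-panel upward bias of sample r2, so an isolated SNP has base LD
#' score 1 and independent SNPs contribute 0 on average.
#'
#' @param panel A [genotype_panel()].
#' @param annot An [annot_matrix()] with rows matching the panel SNPs.
#' @param window_cM One-sided genetic window (default 1 cM).
#' @param chunk Number of SNPs per crossproduct block (memory/speed knob).
#' @return A data frame of class `ldscore_table`: `chr, snp, bp` plus one
#'   `L2.<category>` column per annotation category.
#' @export
compute_ld_scores <- function(panel, annot, window_cM = 1.0, chunk = 512L) {
  stopifnot(inherits(panel, "genotype_panel"))
  n <- panel$n_ind
  if (n <= 2) stop("need more than 2 individuals for adjusted r^2")
  map <- panel$map
  if (nrow(annot) != nrow(map)) stop("annot rows must match panel SNPs")
  C <- ncol(annot)
  out <- matrix(0, nrow(map), C,
                dimnames = list(map$snp, paste0("L2.", colnames(annot))))
  for (ch in unique(map$chr)) {
    idx <- which(map$chr == ch)
    X <- scale(panel$geno[, idx, drop = FALSE])  # n x m, unit sample variance
    cm <- map$cM[idx]
    A <- annot[idx, , drop = FALSE]
    m <- length(idx)
    lo <- findInterval(cm - window_cM, cm, left.open = TRUE) + 1L
    hi <- findInterval(cm + window_cM, cm)
    for (s in seq(1, m, by = chunk)) {
      j <- s:min(s + chunk - 1L, m)
      klo <- min(lo[j]); khi <- max(hi[j])
      k <- klo:khi
      r <- crossprod(X[, k, drop = FALSE], X[, j, drop = FALSE]) / (n - 1)
      r2 <- r * r
      r2 <- r2 - (1 - r2) / (n - 2)
      # zero out pairs beyond the genetic window
      inwin <- outer(cm[k], cm[j], function(a, b) abs(a - b) <= window_cM)
      r2[!inwin] <- 0
      out[idx[j], ] <- out[idx[j], ] + crossprod(r2, A[k, , drop = FALSE])
    }
  }
  df <- data.frame(chr = map$chr, snp = map$snp, bp = map$bp,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(out, check.names = FALSE))
  rownames(df) <- NULL
  class(df) <- c("ldscore_table", "data.frame")
  df
}

ld_categories <- function(ldscores) {
  sub("^L2\\.", "", grep("^L2\\.", names(ldscores), value = TRUE))
}

#' Write / read LDSC-dialect annotation and LD-score tables
#'
#' `.annot`-style files carry `CHR BP SNP CM` plus one 0/1 column per
#' category; `.l2.ldscore`-style files carry `CHR SNP BP` plus `L2.<cat>`
#' columns. Paths ending in `.gz` are transparently gzipped. Round trips are
#' lossless and preserve column order.
#'
#' @param annot An [annot_matrix()].
#' @param map SNP map data frame (`chr`, `snp`, `cM`, `bp`).
#' @param path Output path (append `.gz` for gzip).
#' @name annot_io
#' @export
write_annot <- function(annot, map, path) {
  df <- data.frame(CHR = map$chr, BP = map$bp, SNP = map$snp, CM = map$cM,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(unclass(annot), check.names = FALSE))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname annot_io
#' @return `read_annot`: list with `annot` ([annot_matrix()]) and `map`.
#' @export
read_annot <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  df <- utils::read.table(con, header = TRUE, sep = "\t", check.names = FALSE)
  need <- c("CHR", "BP", "SNP", "CM")
  if (!all(need %in% names(df)))
    stop("malformed annot header: expected columns ",
         paste(need, collapse = " "))
  cats <- setdiff(names(df), need)
  if (!length(cats)) stop("annot file has no category columns")
  m <- as.matrix(df[cats])
  map <- data.frame(chr = df$CHR, snp = df$SNP, cM = df$CM, bp = df$BP)
  list(annot = annot_matrix(m, snp = map$snp), map = map)
}

#' @rdname annot_io
#' @param ldscores An `ldscore_table`.
#' @export
write_ldscore <- function(ldscores, path) {
  df <- ldscores
  names(df)[1:3] <- c("CHR", "SNP", "BP")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname annot_io
#' @export
read_ldscore <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  df <- utils::read.table(con, header = TRUE, sep = "\t", check.names = FALSE)
  need <- c("CHR", "SNP", "BP")
  if (!all(need %in% names(df)) || !any(grepl("^L2\\.", names(df))))
    stop("malformed ldscore header: expected CHR SNP BP and L2.* columns")
  names(df)[match(need, names(df))] <- c("chr", "snp", "bp")
  class(df) <- c("ldscore_table", "data.frame")
  df
}
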