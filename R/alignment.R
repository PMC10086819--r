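#' Nucleotide alignment container
#'
#' A minimal aligned-sequence container: a character matrix (rows = taxa,
#' columns = sites) over A/C/G/T plus IUPAC ambiguity codes, `N`, `-` and `?`.
#'
#' @param x a named character vector of equal-length sequence strings, or a
#'   character matrix with taxon rownames.
#' @return object of class `dna_alignment`.
#' @export
dna_alignment <- function(x) {
  if (is.matrix(x)) {
    m <- toupper(x)
  } else {
    if (is.null(names(x))) stop("sequences must be named by taxon")
    n <- nchar(x)
    if (length(unique(n)) != 1L) stop("sequences differ in length; not aligned")
    if (n[1] < 1L) stop("alignment length must be >= 1")
    m <- matrix(unlist(strsplit(toupper(x), "")), nrow = length(x),
                byrow = TRUE, dimnames = list(names(x), NULL))
  }
  if (is.null(rownames(m))) stop("alignment must carry taxon names")
  if (anyDuplicated(rownames(m))) stop("duplicate taxon labels")
  ok <- m %in% c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-", "?", ".")
  if (!all(ok)) stop("unsupported residue code(s): ",
                     paste(unique(m[!ok]), collapse = " "))
  m[m == "U"] <- "T"
  structure(m, class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("DNA alignment:", nrow(x), "sequences x", ncol(x), "sites\n")
  invisible(x)
}

#' Read / write FASTA alignments
#'
#' Wrappers around [ape::read.FASTA] / plain text writing. Wrapped or
#' single-line FASTA accepted, case-insensitive; `-`, `?` and `N` allowed.
#'
#' @param file path.
#' @return [dna_alignment].
#' @export
read_fasta <- function(file) {
  if (!file.exists(file)) stop("cannot open FASTA file: ", file)
  dn <- ape::read.FASTA(file)
  m <- toupper(as.character(as.matrix(dn)))
  dna_alignment(m)
}

#' @rdname read_fasta
#' @param aln a [dna_alignment].
#' @param width line-wrap width.
#' @export
write_fasta <- function(aln, file, width = 80L) {
  con <- file(file, "w")
  on.exit(close(con))
  for (tx in rownames(aln)) {
    writeLines(paste0(">", tx), con)
    s <- paste(aln[tx, ], collapse = "")
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(file)
}

# IUPAC code -> 4-vector of compatible states (A C G T order)
iupac_partial <- function() {
  codes <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"), `-` = c("A", "C", "G", "T"),
                `?` = c("A", "C", "G", "T"), `.` = c("A", "C", "G", "T"))
  bases <- c("A", "C", "G", "T")
  out <- sapply(codes, function(cc) as.numeric(bases %in% cc))
  rownames(out) <- bases
  out
}

# site-pattern compression; returns tip-partial array restricted to `taxa`
# (in that order), pattern weights, and the per-site pattern index
compress_alignment <- function(aln, taxa) {
  miss <- setdiff(taxa, rownames(aln))
  if (length(miss))
    stop("taxa absent from alignment: ", paste(miss, collapse = ", "))
  m <- unclass(aln)[taxa, , drop = FALSE]
  key <- apply(m, 2, paste, collapse = "")
  u <- !duplicated(key)
  idx <- match(key, key[u])
  wts <- tabulate(idx, nbins = sum(u))
  mp <- m[, u, drop = FALSE]
  lut <- iupac_partial()
  npat <- ncol(mp)
  tip <- array(0, dim = c(4L, npat, length(taxa)))
  for (i in seq_along(taxa)) tip[, , i] <- lut[, mp[i, ]]
  # invariant-compatibility weight per pattern (for the +I mixture)
  list(tip = tip, weights = wts, index = idx, npat = npat)
}

# sum_b pi_b * prod_tips tip(b, pat): invariant-site mixture weight
invariant_weight <- function(tip, bf) {
  pr <- apply(tip, c(1, 2), prod)   # 4 x npat
  as.numeric(crossprod(bf, pr))
}

# empirical base frequencies, ambiguity-aware (shared equally)
empirical_bf <- function(aln) {
  lut <- iupac_partial()
  cnt <- table(factor(unclass(aln), levels = colnames(lut)))
  # fully ambiguous codes (N, gaps, ?) are uninformative; partial ambiguities
  # share their count equally among compatible bases
  inf <- colSums(lut) < 4
  v <- as.numeric(lut[, inf, drop = FALSE] %*%
                    (as.numeric(cnt[inf]) / colSums(lut)[inf]))
  if (sum(v) == 0) return(rep(0.25, 4))
  v / sum(v)
}
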