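# standard genetic code, indexed by codon string
GENETIC_CODE_STD <- local({
  b <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",  # TTT..TGG
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  cods <- as.vector(vapply(b, function(p1)
    vapply(b, function(p2) vapply(b, function(p3)
      paste0(p1, p2, p3), ""), character(4)), matrix("", 4, 4)))
  stats::setNames(aa, cods)
})

codon_aa <- function(cod) unname(GENETIC_CODE_STD[cod])
is_stop <- function(cod) !is.na(GENETIC_CODE_STD[cod]) & GENETIC_CODE_STD[cod] == "*"

# NG86 synonymous/nonsynonymous site counts of one codon: at each position,
# the fraction of the three possible changes that are synonymous; changes to
# stop codons count as nonsynonymous
ng86_sites <- function(cod) {
  bases <- c("A", "C", "G", "T")
  aa0 <- codon_aa(cod)
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(bases, substr(cod, pos, pos))) {
      c2 <- cod
      substr(c2, pos, pos) <- b
      if (!is_stop(c2) && codon_aa(c2) == aa0) s <- s + 1 / 3
    }
  }
  c(S = s, N = 3 - s)
}

# synonymous/nonsynonymous differences between two codons, averaged over
# all minimal substitution pathways; pathways through stop codons are
# excluded (unless all are blocked, in which case all pathways count)
ng86_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  d <- length(pos)
  if (d == 0L) return(c(Sd = 0, Nd = 0))
  perms <- all_perms(pos)
  count_path <- function(ord) {
    cur <- c1
    sd <- 0; nd <- 0
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (is_stop(nxt)) return(NULL)
      if (codon_aa(cur) == codon_aa(nxt)) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null), lapply(perms, count_path))
  if (!length(res)) {  # every pathway blocked by a stop: count them all
    res <- lapply(perms, function(ord) {
      cur <- c1; sd <- 0; nd <- 0
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (codon_aa(cur) == codon_aa(nxt)) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    })
  }
  m <- do.call(rbind, res)
  c(Sd = mean(m[, 1]), Nd = mean(m[, 2]))
}

all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in all_perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

#' Pairwise synonymous divergence by the NG86 counting estimator
#'
#' Counts synonymous and nonsynonymous sites per codon (averaged over the
#' two sequences) and differences averaged over all minimal substitution
#' pathways, then applies the Jukes-Cantor correction
#' `d = -3/4 log(1 - 4p/3)` to the proportions. A synonymous proportion
#' `pS >= 3/4` is flagged saturated (`dS = NA`).
#'
#' @param pair a [dna_alignment] with exactly two rows, length divisible by
#'   3, reading frame at position 1. Codon columns containing gaps or
#'   ambiguity codes are excluded from the counts.
#' @return object of class `ds_result`: list with `dS`, `dN`, `S_sites`,
#'   `N_sites`, `Sd`, `Nd`, `codons` (countable codons) and `saturated`.
#' @export
ng86_ds <- function(pair) {
  stopifnot(inherits(pair, "dna_alignment"))
  if (nrow(pair) != 2L) stop("need exactly two sequences")
  if (ncol(pair) %% 3L != 0L)
    stop("frame violation: alignment length not divisible by 3")
  m <- unclass(pair)
  ncod <- ncol(m) / 3L
  S <- N <- Sd <- Nd <- 0
  counted <- 0L
  for (j in seq_len(ncod)) {
    c1 <- paste(m[1, (3 * j - 2):(3 * j)], collapse = "")
    c2 <- paste(m[2, (3 * j - 2):(3 * j)], collapse = "")
    if (grepl("[^ACGT]", c1) || grepl("[^ACGT]", c2)) next
    if (is_stop(c1) || is_stop(c2)) {
      if (j == ncod) next   # terminal stop codon: ignore
      stop("internal stop codon at codon ", j)
    }
    s1 <- ng86_sites(c1); s2 <- ng86_sites(c2)
    S <- S + (s1["S"] + s2["S"]) / 2
    N <- N + (s1["N"] + s2["N"]) / 2
    dd <- ng86_diffs(c1, c2)
    Sd <- Sd + dd["Sd"]; Nd <- Nd + dd["Nd"]
    counted <- counted + 1L
  }
  if (counted == 0L) stop("zero countable codons")
  pS <- unname(Sd / S)
  pN <- unname(Nd / N)
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 * p / 3)
  structure(list(dS = jc(pS), dN = jc(pN),
                 S_sites = unname(S), N_sites = unname(N),
                 Sd = unname(Sd), Nd = unname(Nd), codons = counted,
                 saturated = pS >= 3 / 4),
            class = "ds_result")
}

#' @export
print.ds_result <- function(x, ...) {
  cat(sprintf("NG86: dS = %s, dN = %s (S = %.2f, N = %.2f sites, %d codons%s)\n",
              format(x$dS, digits = 4), format(x$dN, digits = 4),
              x$S_sites, x$N_sites, x$codons,
              if (x$saturated) ", SATURATED" else ""))
  invisible(x)
}

#' Extract the focal Z/W coding pair from a gene alignment
#'
#' Pulls the two named rows and drops every codon column containing a gap or
#' ambiguity code in either sequence, keeping the reading frame (frame is
#' taken to start at alignment position 1).
#'
#' @param aln a [dna_alignment].
#' @param z_label,w_label row names of the focal Z and W sequences.
#' @return a two-row [dna_alignment] of complete codon columns.
#' @export
extract_focal_pair <- function(aln, z_label, w_label) {
  miss <- setdiff(c(z_label, w_label), rownames(aln))
  if (length(miss)) stop("labels absent: ", paste(miss, collapse = ", "))
  m <- unclass(aln)[c(z_label, w_label), , drop = FALSE]
  if (ncol(m) %% 3L != 0L)
    stop("frame cannot be established: length not divisible by 3")
  keep <- logical(0)
  for (j in seq_len(ncol(m) / 3L)) {
    blk <- m[, (3 * j - 2):(3 * j)]
    keep <- c(keep, rep(all(blk %in% c("A", "C", "G", "T")), 3L))
  }
  dna_alignment(m[, keep, drop = FALSE])
}
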