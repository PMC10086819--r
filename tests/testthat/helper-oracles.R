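# independent oracles shared between unit and acceptance tests

# independent pathway-enumeration oracle for NG86 on a codon pair list
ng86_oracle <- function(cod1, cod2) {
  code <- trcest:::GENETIC_CODE_STD
  bases <- c("A", "C", "G", "T")
  syn_sites_codon <- function(cod) {
    s <- 0
    for (pos in 1:3) for (b in bases) {
      if (b == substr(cod, pos, pos)) next
      c2 <- cod; substr(c2, pos, pos) <- b
      if (code[c2] != "*" && code[c2] == code[cod]) s <- s + 1 / 3
    }
    s
  }
  path_counts <- function(c1, c2, allow_stop) {
    difpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(difpos)) return(matrix(0, 1, 2))
    perms <- if (length(difpos) == 1) list(difpos)
             else if (length(difpos) == 2) list(difpos, rev(difpos))
             else {
               p <- list()
               for (a in difpos) for (b in setdiff(difpos, a))
                 p[[length(p) + 1]] <- c(a, b, setdiff(difpos, c(a, b)))
               p
             }
    out <- NULL
    for (ord in perms) {
      cur <- c1; sd <- 0; nd <- 0; ok <- TRUE
      for (p in ord) {
        nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
        if (code[nxt] == "*" && !allow_stop) { ok <- FALSE; break }
        if (code[cur] == code[nxt]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (ok) out <- rbind(out, c(sd, nd))
    }
    out
  }
  S <- N <- Sd <- Nd <- 0
  for (i in seq_along(cod1)) {
    s1 <- syn_sites_codon(cod1[i]); s2 <- syn_sites_codon(cod2[i])
    S <- S + (s1 + s2) / 2
    N <- N + (3 - s1 + 3 - s2) / 2
    pc <- path_counts(cod1[i], cod2[i], allow_stop = FALSE)
    if (is.null(pc)) pc <- path_counts(cod1[i], cod2[i], allow_stop = TRUE)
    Sd <- Sd + mean(pc[, 1]); Nd <- Nd + mean(pc[, 2])
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd, dS = jc(Sd / S), dN = jc(Nd / N))
}

random_codons <- function(n, seed) {
  set.seed(seed)
  code <- trcest:::GENETIC_CODE_STD
  ok <- names(code)[code != "*"]
  sample(ok, n, replace = TRUE)
}


# exhaustive two-cluster optimum by enumerating all binary partitions
best_partition_cost <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  best <- Inf
  for (mask in 1:(2^n - 2)) {
    g <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    c1 <- colMeans(x[g, , drop = FALSE])
    c2 <- colMeans(x[!g, , drop = FALSE])
    cost <- sum(sweep(x[g, , drop = FALSE], 2, c1)^2) +
      sum(sweep(x[!g, , drop = FALSE], 2, c2)^2)
    best <- min(best, cost)
  }
  best
}


# LP optimal-transport oracle for the 1-D quadratic Wasserstein distance
lp_transport_w2 <- function(a, b) {
  n <- length(a); m <- length(b)
  C <- outer(sort(a), sort(b), function(u, v) (u - v)^2)
  A <- rbind(t(sapply(seq_len(n), function(i) {
    z <- matrix(0, n, m); z[i, ] <- 1; as.vector(z)
  })), t(sapply(seq_len(m), function(j) {
    z <- matrix(0, n, m); z[, j] <- 1; as.vector(z)
  })))
  # drop the redundant last equality row (rank n + m - 1)
  lp <- pracma::linprog(as.vector(C), Aeq = A[-(n + m), ],
                        beq = c(rep(1 / n, n), rep(1 / m, m))[-(n + m)],
                        maxiter = 500)
  sqrt(lp$fval)
}
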