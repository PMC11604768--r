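## Independent reference implementations used as oracles. These stay
## deliberately naive (string loops, O(n^2) scans) and share no code with
## the package internals they check.

## two-pass seed resolution: trim flanking N runs, then per-position argmax
## over the bases the IUPAC code permits (alphabetical tie-break)
oracle_resolve <- function(seed, pwm) {
  codes <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T")
  )
  ch <- strsplit(seed, "")[[1]]
  i <- 1
  while (i <= length(ch) && ch[i] == "N") i <- i + 1
  j <- length(ch)
  while (j >= 1 && ch[j] == "N") j <- j - 1
  if (i > j) stop("all N")
  out <- character(0)
  for (k in i:j) {
    allowed <- codes[[ch[k]]]
    if (length(allowed) == 1) {
      out <- c(out, allowed)
    } else {
      w <- pwm[k, match(allowed, c("A", "C", "G", "T"))]
      out <- c(out, allowed[which.max(w)])
    }
  }
  paste(out, collapse = "")
}

## O(n^2) substring-containment filter, first-wins on exact duplicates
oracle_dedup <- function(seqs) {
  n <- length(seqs)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (seqs[j] != seqs[i] && grepl(seqs[i], seqs[j], fixed = TRUE)) {
        keep[i] <- FALSE
      }
      if (seqs[j] == seqs[i] && j < i) keep[i] <- FALSE
    }
  }
  seqs[keep]
}

## brute-force greedy sphere clustering on a (barcode, count) data frame
oracle_sphere <- function(tally, radius) {
  ord <- order(-tally$count, tally$barcode)
  bc <- tally$barcode[ord]
  ct <- tally$count[ord]
  assigned <- rep(FALSE, length(bc))
  out <- NULL
  while (any(!assigned)) {
    i <- which(!assigned)[1]
    members <- integer(0)
    for (j in which(!assigned)) {
      if (utils::adist(bc[i], bc[j])[1, 1] <= radius) members <- c(members, j)
    }
    assigned[members] <- TRUE
    out <- rbind(out, data.frame(centroid = bc[i], barcode = bc[members],
                                 count = ct[members]))
  }
  out
}

## random tally of near-collision 24-mers (mutations of few cores) so that
## radius-1 clustering actually merges things
random_tally <- function(n, n_cores = 6) {
  cores <- replicate(n_cores, paste(sample(c("A", "C", "G", "T"), 24,
                                           replace = TRUE), collapse = ""))
  bcs <- character(0)
  while (length(bcs) < n) {
    b <- strsplit(sample(cores, 1), "")[[1]]
    k <- sample(0:2, 1)
    if (k > 0) {
      pos <- sample(24, k)
      b[pos] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    }
    bcs <- unique(c(bcs, paste(b, collapse = "")))
  }
  data.frame(barcode = bcs[seq_len(n)],
             count = sample(1:50, n, replace = TRUE))
}

## brute-force NB log-likelihood maximizer for one promoter (oracle for the
## vectorized engine): free effect per condition (or shared), dispersion
## profiled, all via optim on dnbinom
oracle_nb_fit <- function(y, offset, cond, shared = FALSE, fixed_size = NULL) {
  K <- if (shared) 1L else length(unique(cond))
  cid <- if (shared) rep(1L, length(cond)) else as.integer(factor(cond))
  nll <- function(par) {
    beta <- par[seq_len(K)]
    size <- if (is.null(fixed_size)) exp(par[K + 1]) else fixed_size
    mu <- offset * exp(beta[cid])
    -sum(dnbinom(y, mu = mu, size = size, log = TRUE))
  }
  init <- rep(log(pmax(sum(y), 1) / sum(offset)), K)
  if (is.null(fixed_size)) init <- c(init, log(5))
  fit <- optim(init, nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  list(loglik = -fit$value, beta = fit$par[seq_len(K)],
       phi = if (is.null(fixed_size)) 1 / exp(fit$par[K + 1]) else
         1 / fixed_size)
}

## tiny deterministic count scenario builder for quantification tests
toy_counts <- function(mat, samples) {
  tibble::tibble(
    barcode = rep(rownames(mat), ncol(mat)),
    sample_id = rep(colnames(mat), each = nrow(mat)),
    count = as.integer(mat)
  )
}
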