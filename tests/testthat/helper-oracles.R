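# Independent oracles used across the suite. Each reimplements a result
# from first principles, by a different route than the package code.

# --- peptide partition: brute-force per-residue set intersection ----------
oracle_assign <- function(catalog, annotations) {
  vapply(seq_len(nrow(catalog)), function(k) {
    pep <- seq.int(catalog$start[k], catalog$end[k])
    ann <- annotations[annotations$accession == catalog$accession[k], ,
                       drop = FALSE]
    vp1 <- ann[ann$chain_name == "VP1", , drop = FALSE]
    vp1_res <- unlist(lapply(seq_len(nrow(vp1)),
                             function(r) seq.int(vp1$start[r], vp1$end[r])))
    ce1_res <- unlist(lapply(seq_len(nrow(vp1)), function(r) {
      if (is.na(vp1$ce1_start[r])) integer(0)
      else seq.int(vp1$ce1_start[r], vp1$ce1_end[r])
    }))
    if (length(intersect(pep, ce1_res)) >= 1) "CE1_VP1"
    else if (length(intersect(pep, vp1_res)) >= 1) "NON_CE1_VP1"
    else "NON_VP1"
  }, character(1))
}

# --- normalized Shannon entropy, direct evaluation ------------------------
oracle_arb <- function(ebs_row) {
  p <- ebs_row / sum(ebs_row)
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(ebs_row))
}

# --- Smith-Waterman: top-down memoized recursion over suffix states -------
# Score of the best local alignment; written as a recursion on "best
# alignment ending at (i, j) in state H/E/F", independent of the package's
# bottom-up C++ implementation.
oracle_sw <- function(q, s, sub, open = 11L, ext = 1L) {
  qi <- strsplit(q, "")[[1]]
  si <- strsplit(s, "")[[1]]
  m <- length(qi); n <- length(si)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, state) {
    if (i < 1 || j < 1) return(if (state == "H") 0 else -Inf)
    key <- paste(i, j, state)
    if (exists(key, envir = memo, inherits = FALSE)) {
      return(get(key, envir = memo))
    }
    val <- if (state == "H") {
      max(0,
          rec(i - 1, j - 1, "H") + sub[qi[i], si[j]],
          rec(i, j, "E"),
          rec(i, j, "F"))
    } else if (state == "E") {
      max(rec(i, j - 1, "H") - open - ext, rec(i, j - 1, "E") - ext)
    } else {
      max(rec(i - 1, j, "H") - open - ext, rec(i - 1, j, "F") - ext)
    }
    assign(key, val, envir = memo)
    val
  }
  best <- 0
  for (i in seq_len(m)) for (j in seq_len(n)) best <- max(best, rec(i, j, "H"))
  best
}

# Fully exhaustive path enumeration for tiny sequences; validates oracle_sw.
oracle_sw_enum <- function(q, s, sub, open = 11L, ext = 1L) {
  qi <- strsplit(q, "")[[1]]
  si <- strsplit(s, "")[[1]]
  best <- 0
  walk <- function(i, j, score, last) {
    best <<- max(best, score)
    if (i < length(qi) && j < length(si)) {
      walk(i + 1, j + 1, score + sub[qi[i + 1], si[j + 1]], "M")
    }
    if (i < length(qi)) {
      walk(i + 1, j, score - (if (last == "U") ext else open + ext), "U")
    }
    if (j < length(si)) {
      walk(i, j + 1, score - (if (last == "L") ext else open + ext), "L")
    }
  }
  for (i in seq_along(qi)) for (j in seq_along(si)) {
    walk(i, j, sub[qi[i], si[j]], "M")
  }
  best
}

# --- logistic regression: Newton-Raphson IRLS at high precision -----------
oracle_logistic <- function(x, y, tol = 1e-12, maxit = 100) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    step <- solve(t(X) %*% (W * X), t(X) %*% (y - mu))
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# --- Kaplan-Meier and two-sample log-rank from first principles -----------
oracle_km <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  surv <- numeric(length(tt)); sgo <- 1
  for (k in seq_along(tt)) {
    at_risk <- sum(time >= tt[k])
    d <- sum(time == tt[k] & event == 1)
    sgo <- sgo * (1 - d / at_risk)
    surv[k] <- sgo
  }
  data.frame(time = tt, surv = surv)
}

oracle_logrank <- function(time, event, group) {
  g <- unique(group)
  stopifnot(length(g) == 2)
  tt <- sort(unique(time[event == 1]))
  o_e <- 0; v <- 0
  for (tk in tt) {
    n1 <- sum(time >= tk & group == g[1])
    n2 <- sum(time >= tk & group == g[2])
    d1 <- sum(time == tk & event == 1 & group == g[1])
    d2 <- sum(time == tk & event == 1 & group == g[2])
    n <- n1 + n2; d <- d1 + d2
    if (n < 2) next
    o_e <- o_e + (d1 - d * n1 / n)
    v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  o_e^2 / v
}

# --- Spearman rho by direct rank computation (mid-ranks) ------------------
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# --- random catalog builder used by partition property tests --------------
random_catalog <- function(n_pep, annotations, seed) {
  set.seed(seed)
  accs <- unique(annotations$accession)
  acc <- sample(accs, n_pep, replace = TRUE)
  len <- sample(1:80, n_pep, replace = TRUE)
  maxlen <- tapply(annotations$end, annotations$accession, max)
  start <- vapply(seq_len(n_pep), function(k) {
    sample.int(maxlen[[acc[k]]] - len[k] + 1L, 1L)
  }, integer(1))
  data.frame(peptide_id = sprintf("r%04d", seq_len(n_pep)),
             accession = acc, start = start, end = start + len - 1L,
             strain = "s", stringsAsFactors = FALSE)
}
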