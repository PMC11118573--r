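# Independent brute-force oracles used to validate the alignment and
# identity implementations. These are written as plain, full-matrix dynamic
# programs with explicit loops; they share only the stated conventions
# (gap of length L costs open + (L-1)*extend; tie-breaks diag > up > left;
# final state M > D > I) with the package, not any code.

oracle_dna_matrix <- function() {
  ab <- c("A", "C", "G", "T", "N")
  m <- matrix(-3, 5, 5, dimnames = list(ab, ab))
  diag(m) <- 1
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

oracle_blosum <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V","X","*")
  m <- matrix(0, 22, 22, dimnames = list(aa, aa))
  m[aa[1:20], aa[1:20]] <- e$BLOSUM62[aa[1:20], aa[1:20]]
  for (a in aa) { m["*", a] <- -4; m[a, "*"] <- -4 }
  m["*", "*"] <- 1
  for (a in aa) { m["X", a] <- 0; m[a, "X"] <- 0 }
  m
}

# full-matrix Gotoh with explicit per-cell pointer bookkeeping
oracle_align <- function(ref, qry, smat, open, ext) {
  r <- strsplit(ref, "")[[1]]
  q <- strsplit(qry, "")[[1]]
  n <- length(r); m <- length(q)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1); D <- matrix(NEG, n + 1, m + 1); I <- matrix(NEG, n + 1, m + 1)
  pM <- matrix("", n + 1, m + 1); pD <- matrix("", n + 1, m + 1); pI <- matrix("", n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) { D[i + 1, 1] <- -(open + (i - 1) * ext); pD[i + 1, 1] <- if (i == 1) "M" else "D" }
  for (j in seq_len(m)) { I[1, j + 1] <- -(open + (j - 1) * ext); pI[1, j + 1] <- if (j == 1) "M" else "I" }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- smat[r[i], q[j]]
      cand <- c(M = M[i, j], D = D[i, j], I = I[i, j])
      best <- names(cand)[which.max(cand)]  # ties: M, then D, then I
      M[i + 1, j + 1] <- cand[[best]] + s
      pM[i + 1, j + 1] <- best
      if (M[i, j + 1] - open >= D[i, j + 1] - ext) {
        D[i + 1, j + 1] <- M[i, j + 1] - open; pD[i + 1, j + 1] <- "M"
      } else {
        D[i + 1, j + 1] <- D[i, j + 1] - ext; pD[i + 1, j + 1] <- "D"
      }
      if (M[i + 1, j] - open >= I[i + 1, j] - ext) {
        I[i + 1, j + 1] <- M[i + 1, j] - open; pI[i + 1, j + 1] <- "M"
      } else {
        I[i + 1, j + 1] <- I[i + 1, j] - ext; pI[i + 1, j + 1] <- "I"
      }
    }
  }
  fin <- c(M = M[n + 1, m + 1], D = D[n + 1, m + 1], I = I[n + 1, m + 1])
  state <- names(fin)[which.max(fin)]
  score <- fin[[state]]
  ar <- character(); aq <- character()
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (state == "M") {
      ar <- c(r[i], ar); aq <- c(q[j], aq)
      state <- pM[i + 1, j + 1]; i <- i - 1; j <- j - 1
    } else if (state == "D") {
      ar <- c(r[i], ar); aq <- c("-", aq)
      state <- pD[i + 1, j + 1]; i <- i - 1
    } else {
      ar <- c("-", ar); aq <- c(q[j], aq)
      state <- pI[i + 1, j + 1]; j <- j - 1
    }
  }
  list(aligned_ref = paste(ar, collapse = ""), aligned_qry = paste(aq, collapse = ""),
       score = score)
}

# column-walk gap-compressed identity, written independently of the package
oracle_gc_identity <- function(aligned_ref, aligned_qry) {
  r <- strsplit(aligned_ref, "")[[1]]
  q <- strsplit(aligned_qry, "")[[1]]
  stop_col <- 0L
  for (k in seq_along(q)) if (q[k] == "*") { stop_col <- k; break }
  keep <- if (stop_col > 0) seq_len(stop_col) else seq_along(q)
  matches <- 0; denom <- 0; in_refgap <- FALSE
  for (k in keep) {
    if (r[k] == "-") {
      if (!in_refgap) denom <- denom + 1
      in_refgap <- TRUE
    } else {
      in_refgap <- FALSE
      denom <- denom + 1
      if (r[k] == q[k]) matches <- matches + 1
    }
  }
  if (denom == 0) 0 else matches / denom
}

rand_protein <- function(len) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V"), len, replace = TRUE), collapse = "")
}
rand_dna <- function(len) paste(sample(c("A","C","G","T"), len, replace = TRUE), collapse = "")
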