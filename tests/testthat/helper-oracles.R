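# Independent oracles and small fixtures shared across the suite. Each
# oracle is a deliberately naive implementation kept separate from the
# package's code paths.

# ---- published Grantham (1974) integer table, transcribed as printed ----
# Row/column order as in the original publication; lower triangle.
grantham_published_fixture <- local({
  txt <- "
res  S   R   L   P   T   A   V   G   I   F   Y   C   H   Q   N   K   D   E   M
R   110   .   .   .   .   .   .   .   .   .   .   .   .   .   .   .   .   .   .
L   145 102   .   .   .   .   .   .   .   .   .   .   .   .   .   .   .   .   .
P    74 103  98   .   .   .   .   .   .   .   .   .   .   .   .   .   .   .   .
T    58  71  92  38   .   .   .   .   .   .   .   .   .   .   .   .   .   .   .
A    99 112  96  27  58   .   .   .   .   .   .   .   .   .   .   .   .   .   .
V   124  96  32  68  69  64   .   .   .   .   .   .   .   .   .   .   .   .   .
G    56 125 138  42  59  60 109   .   .   .   .   .   .   .   .   .   .   .   .
I   142  97   5  95  89  94  29 135   .   .   .   .   .   .   .   .   .   .   .
F   155  97  22 114 103 113  50 153  21   .   .   .   .   .   .   .   .   .   .
Y   144  77  36 110  92 112  55 147  33  22   .   .   .   .   .   .   .   .   .
C   112 180 198 169 149 195 192 159 198 205 194   .   .   .   .   .   .   .   .
H    89  29  99  77  47  86  84  98  94 100  83 174   .   .   .   .   .   .   .
Q    68  43 113  76  42  91  96  87 109 116  99 154  24   .   .   .   .   .   .
N    46  86 153  91  65 111 133  80 149 158 143 139  68  46   .   .   .   .   .
K   121  26 107 103  78 106  97 127 102 102  85 202  32  53  94   .   .   .   .
D    65  96 172 108  85 126 152  94 168 177 160 154  81  61  23 101   .   .   .
E    80  54 138  93  65 107 121  98 134 140 122 170  40  29  42  56  45   .   .
M   135  91  15  87  81  84  21 127  10  28  36 196  87 101 142  95 160 126   .
W   177 101  61 147 128 148  88 184  61  40  37 215 115 130 174 110 181 152  67"
  tab <- utils::read.table(text = txt, header = TRUE, row.names = 1,
                           na.strings = ".", check.names = FALSE)
  aa <- c(colnames(tab), "W")
  m <- matrix(0, 20L, 20L, dimnames = list(aa, aa))
  for (r in rownames(tab)) {
    for (cn in colnames(tab)) {
      v <- tab[r, cn]
      if (!is.na(v)) {
        m[r, cn] <- v
        m[cn, r] <- v
      }
    }
  }
  m
})

# ---- dynamic-programming Levenshtein oracle ----
levenshtein_oracle <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x)
  m <- length(y)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- if (x[i] == y[j]) 0L else 1L
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + cost)
    }
  }
  d[n + 1, m + 1]
}

# ---- Cox partial-likelihood oracle (single binary covariate, no ties) ----
cox_beta_oracle <- function(time, event, x) {
  stopifnot(!anyDuplicated(time[event == 1]))
  nll <- function(beta) {
    val <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      val <- val - (beta * x[i] - log(sum(exp(beta * x[risk]))))
    }
    val
  }
  stats::optimize(nll, c(-10, 10), tol = 1e-10)$minimum
}

# ---- two-group log-rank statistic oracle ----
logrank_p_oracle <- function(time, event, group) {
  stopifnot(all(group %in% c(0, 1)))
  times <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == 1)
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  chisq <- o_minus_e^2 / v
  stats::pchisq(chisq, df = 1, lower.tail = FALSE)
}

# ---- brute-force Youden oracle ----
youden_oracle <- function(scores, labels) {
  best_j <- -Inf
  best_t <- NA
  for (t in sort(unique(scores))) {
    sens <- sum(scores >= t & labels == 1) / sum(labels == 1)
    spec <- sum(scores < t & labels == 0) / sum(labels == 0)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) {
      best_j <- j
      best_t <- t
    }
  }
  list(threshold = best_t, j = best_j)
}

# ---- tiny fixtures ----
# alignment of 181 columns differing at exactly one site with d(S, R) = 110
toy_allele_store <- function() {
  base <- strsplit(paste(rep("ACDEFGHIKLMNPQRSTVWY", 10), collapse = ""),
                   "")[[1]][1:181]
  s1 <- base
  s2 <- base
  s1[91] <- "S"
  s2[91] <- "R"
  tibble::tibble(
    allele = c("A*01:01", "A*02:01", "B*07:02", "B*08:01",
               "C*07:01", "C*07:02"),
    sequence = c(paste(s1, collapse = ""), paste(s2, collapse = ""),
                 paste(s1, collapse = ""), paste(s2, collapse = ""),
                 paste(s1, collapse = ""), paste(s2, collapse = ""))
  )
}

toy_genotype <- function(patient_id = "P1",
                         A1 = "A*01:01", A2 = "A*02:01",
                         B1 = "B*07:02", B2 = "B*08:01",
                         C1 = "C*07:01", C2 = "C*07:02") {
  tibble::tibble(patient_id = patient_id, A1 = A1, A2 = A2,
                 B1 = B1, B2 = B2, C1 = C1, C2 = C2)
}

random_survival_cohort <- function(n, seed, hr = 1, censor = 0.2) {
  withr::with_seed(seed, {
    grp <- rbinom(n, 1, 0.5)
    t_event <- rexp(n, 0.05 * ifelse(grp == 1, hr, 1))
    cens <- runif(n) < censor
    tibble::tibble(
      patient_id = seq_len(n),
      os_months = ifelse(cens, t_event * runif(n), t_event),
      os_event = as.integer(!cens),
      grp = grp
    )
  })
}
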