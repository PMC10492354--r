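# Shared fixtures and independent oracles for the test suite.

# random row-stochastic membership matrix
rand_U <- function(n, k) {
  U <- matrix(stats::rexp(n * k), n, k)
  U / rowSums(U)
}

# two well-separated planted groups in p dimensions (binary-ish features)
two_blob_data <- function(n = 200, p = 4, flip = 0.05, seed = 42) {
  set.seed(seed)
  half <- n %/% 2
  proto <- rbind(c(rep(1, p / 2), rep(0, p - p / 2)),
                 c(rep(0, p / 2), rep(1, p - p / 2)))
  lab <- rep(1:2, c(half, n - half))
  X <- proto[lab, ]
  noise <- matrix(stats::runif(n * p) < flip, n, p)
  X <- abs(X - noise)
  rownames(X) <- sprintf("b%03d", seq_len(n))
  list(X = X, labels = lab)
}

# one encounter row with defaults, for hand-built fixtures
enc_row <- function(patient_id, age = 70, sex = "female",
                    specialty = "cardiology", code = "X1",
                    group = "Cardiac dysrhythmias", type = "chronic",
                    outpatient = 1, ed = 0, inpatient = 0) {
  data.frame(patient_id = patient_id, age_years = age, sex = sex,
             specialty = specialty, diagnosis_code = code,
             diagnosis_group = group, diagnosis_type = type,
             outpatient_visits = outpatient, ed_visits = ed,
             inpatient_days = inpatient, stringsAsFactors = FALSE)
}

# fixture covering every printed inclusion disjunct plus each exclusion mode
inclusion_fixture <- function() {
  rbind(
    # two chronic diagnoses with outpatient care -> included
    enc_row("two_chronic", code = "A1"),
    enc_row("two_chronic", code = "A2", specialty = "neurology"),
    # two oncological diagnoses -> included
    enc_row("two_onc", code = "B1", type = "oncological"),
    enc_row("two_onc", code = "B2", type = "oncological"),
    # one chronic + one oncological -> included
    enc_row("chronic_onc", code = "D1", type = "chronic"),
    enc_row("chronic_onc", code = "D2", type = "oncological"),
    # minor with three chronic diagnoses -> excluded
    enc_row("minor", age = 17, code = "E1"),
    enc_row("minor", age = 17, code = "E2"),
    enc_row("minor", age = 17, code = "E3"),
    # only acute diagnoses -> excluded
    enc_row("acute_only", code = "F1", type = "acute"),
    enc_row("acute_only", code = "F2", type = "acute"),
    # two chronic diagnoses but no outpatient visits -> excluded
    enc_row("no_visits", code = "G1", outpatient = 0, ed = 1),
    enc_row("no_visits", code = "G2", outpatient = 0, ed = 1),
    # single chronic diagnosis -> excluded
    enc_row("one_chronic", code = "H1"))
}

# brute-force check of the three printed inclusion disjuncts per patient
bf_included <- function(enc, min_age = 18, require_visit = TRUE) {
  vapply(unique(enc$patient_id), function(id) {
    d <- enc[enc$patient_id == id, ]
    if (d$age_years[1] < min_age) return(FALSE)
    ok <- if (require_visit) d$outpatient_visits >= 1 else rep(TRUE, nrow(d))
    n_chronic <- length(unique(d$diagnosis_code[ok & d$diagnosis_type == "chronic"]))
    n_onc <- length(unique(d$diagnosis_code[ok & d$diagnosis_type == "oncological"]))
    n_chronic >= 2 || n_onc >= 2 || (n_chronic >= 1 && n_onc >= 1)
  }, logical(1))
}

# exhaustive pairwise silhouette, crisp labels
bf_silhouette <- function(X, labels) {
  n <- nrow(X)
  d <- as.matrix(stats::dist(X))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# independently coded direct band-pattern classifier (the banding oracle):
# classify every membership into its band, then key the patient by all
# significant bands, except that a full membership absorbs everything
bf_band_pattern <- function(u) {
  band <- character(length(u))
  band[u >= 0.8] <- "FULL"
  band[u >= 0.6 & u < 0.8] <- "DOM"
  band[u >= 0.4 & u < 0.6] <- "MID"
  band[u >= 0.2 & u < 0.4] <- "LOW"
  band[u < 0.2] <- ""
  if (any(band == "FULL")) {
    j <- which(band == "FULL")
    return(paste0(j, ":FULL"))
  }
  sig <- which(band != "")
  if (length(sig) == 0) return("REST")
  paste(sprintf("%d:%s", sig, band[sig]), collapse = "+")
}

# Monte-Carlo brute-force FCM oracle for k = 2: best cost over B random
# membership matrices, each completed with its optimal centroids
bf_mc_best_cost <- function(X, m, B = 1e5) {
  n <- nrow(X)
  E1 <- matrix(stats::rexp(B * n), B, n)
  E2 <- matrix(stats::rexp(B * n), B, n)
  W1 <- E1 / (E1 + E2)
  W2 <- 1 - W1
  cost_one <- function(W) {
    Wm <- W^m
    Cw <- (Wm %*% X) / rowSums(Wm)          # B x p optimal centroids
    D <- 0
    for (j in seq_len(ncol(X)))
      D <- D + (outer(Cw[, j], X[, j], "-"))^2
    rowSums(Wm * D)
  }
  min(cost_one(W1) + cost_one(W2))
}
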