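# shared helpers for building tiny fixtures in code

make_sheet <- function(points, doc = "D1", inst = "PERSONALIZATION",
                       rater = "R1") {
  if (is.null(names(points))) {
    names(points) <- names(instrument_definition(inst)$dimensions)
  }
  score_sheet(doc, inst, rater, points)
}

# tiny consolidated guideline table with known weighted scores
tiny_table <- function() {
  read_guidelines(data.frame(
    treatment_id = c("T1", "T2", "T3"),
    name = c("a", "b", "c"),
    ACR = c("SR", "CR", "SRA"), OARSI = c("SR", "CR", "SRA"),
    ESCEO = c("SR", "CR", NA), AAOS = c("SR", NA, NA),
    NICE = c("SR", NA, NA), stringsAsFactors = FALSE))
  # T1: SR x5 -> +2 * 1 = 2 ; T2: CR x3 -> +1 * 0.75 ; T3: SRA x2 -> -2 * 0.5
}

# independent brute-force recomputation of a document accuracy score from
# raw stances (used as oracle against the vectorized path)
brute_accuracy <- function(mention_ids, raw_tab) {
  total <- 0
  for (id in unique(mention_ids)) {
    st <- unlist(raw_tab[raw_tab$treatment_id == id,
                         c("ACR", "OARSI", "ESCEO", "AAOS", "NICE")])
    st <- st[!is.na(st) & st != "NOT_ADDRESSED"]
    counts <- table(st)
    top <- max(counts)
    cat_mod <- if (sum(counts == top) > 1L) "INC" else names(which.max(counts))
    sc <- c(SR = 2, CR = 1, INC = 0, CRA = -1, SRA = -2)[[cat_mod]]
    wt <- if (top >= 4) 1 else c(0.25, 0.5, 0.75)[top]
    total <- total + sc * wt
  }
  total
}

# brute-force exact two-sided signed-rank p over all 2^n sign patterns
brute_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    signs <- as.logical(bitwAnd(m, 2^(0:(n - 1))))
    vs[m + 1] <- sum(r[signs])
  }
  min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
}
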