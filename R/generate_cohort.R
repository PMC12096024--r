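#' Generate a synthetic guideline table
#'
#' Builds a table of `n_treatments` treatments with per-society stances
#' constructed to realize a planned consolidated category and consensus
#' level, then consolidated through [read_guidelines()]. For `n >= 8` every
#' consensus-weight class (1, 0.75, 0.5, 0.25) is represented. Reproducible:
#' the same seed gives an identical table.
#'
#' @param n_treatments Number of treatments, >= 1.
#' @param seed Optional integer seed.
#' @return Consolidated guideline table (as from [read_guidelines()]).
#' @export
generate_guideline_table <- function(n_treatments, seed = NULL) {
  stopifnot(n_treatments >= 1)
  if (!is.null(seed)) set.seed(seed)
  labels <- treatment_labels()
  labels <- rep_len(paste0(labels, ""), n_treatments)
  labels <- make.unique(labels, sep = " variant ")
  # first eight treatments span every weight class and both recommendation
  # directions, as real guideline tables do (so planted accuracy targets have
  # positive score mass to work with); the rest are random
  planned_n <- c(5L, 4L, 3L, 2L, 1L, 3L, 2L, 4L)
  planned_cat <- c("SR", "SR", "CR", "CR", "CRA", "INC", "SRA", "CR")
  n_planned <- min(8L, n_treatments)
  consensus_plan <- c(planned_n[seq_len(n_planned)],
                      if (n_treatments > 8L)
                        sample(1:5, n_treatments - 8L, replace = TRUE))
  category_plan <- c(planned_cat[seq_len(n_planned)],
                     if (n_treatments > 8L)
                       sample(stance_levels, n_treatments - 8L,
                              replace = TRUE))
  rows <- lapply(seq_len(n_treatments), function(i) {
    k <- consensus_plan[i]
    cat_i <- category_plan[i]
    stances <- rep(NA_character_, 5L)
    members <- sample(5L, k)
    stances[members] <- cat_i
    # remaining societies: NOT_ADDRESSED or a distinct minority category
    others <- setdiff(seq_len(5L), members)
    if (k >= 2L && length(others)) {
      minority <- sample(setdiff(stance_levels, cat_i))
      n_min <- sample(0:min(length(others), min(k - 1L, length(minority))), 1L)
      if (n_min > 0L) stances[others[seq_len(n_min)]] <- minority[seq_len(n_min)]
    }
    out <- as.list(stances)
    names(out) <- guideline_societies
    c(list(treatment_id = sprintf("T%02d", i), name = labels[i]), out)
  })
  tab <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  read_guidelines(tab)
}

#' Simulate noisy raters for one true score sheet
#'
#' Each primary rater reports the truth plus rounded Gaussian noise, clipped
#' to the dimension range. With probability `p_disagreement` one randomly
#' chosen dimension of the second rater is pushed strictly past the
#' adjudication threshold, guaranteeing a flag. A third rater close to the
#' truth is always produced for adjudication paths.
#'
#' @param true_sheet A valid [score_sheet()] holding the latent true points.
#' @param noise_sd Rater noise SD in points per dimension.
#' @param p_disagreement Probability of injecting a super-threshold
#'   disagreement.
#' @param seed Optional integer seed.
#' @param threshold Adjudication threshold, default 10.
#' @return List of sheets `r1`, `r2`, `r3`.
#' @export
simulate_raters <- function(true_sheet, noise_sd, p_disagreement = 0,
                            seed = NULL, threshold = 10) {
  if (!is.null(seed)) set.seed(seed)
  def <- instrument_definition(true_sheet$instrument)
  maxima <- def$dimensions[names(true_sheet$points)]
  noisy <- function(rater_id, sd) {
    pts <- round(true_sheet$points + stats::rnorm(length(maxima), 0, sd))
    pts <- pmin(pmax(pts, 0), maxima)
    score_sheet(true_sheet$doc_id, true_sheet$instrument, rater_id, pts)
  }
  r1 <- noisy("R1", noise_sd)
  r2 <- noisy("R2", noise_sd)
  if (p_disagreement > 0 && stats::runif(1) < p_disagreement) {
    j <- sample(length(maxima), 1L)
    bump <- threshold + 1L + sample(0:3, 1L)
    # push away from the nearer bound so the gap survives clipping
    up <- r1$points[[j]] + bump <= maxima[[j]]
    r2$points[[j]] <- if (up) r1$points[[j]] + bump else r1$points[[j]] - bump
    r2$points[[j]] <- min(max(r2$points[[j]], 0), maxima[[j]])
  }
  r3 <- noisy("R3", max(noise_sd / 2, 0.5))
  list(r1 = r1, r2 = r2, r3 = r3)
}

#' Plant a treatment-mention set approximating a target accuracy
#'
#' Randomized greedy subset selection: treatments are visited in random
#' order and included whenever inclusion moves the running weighted sum
#' closer to the target. The achieved sum differs from the target by
#' quantization-scale noise, which is the generator's (document-level)
#' accuracy variability.
#'
#' @param table Consolidated guideline table.
#' @param target Target raw accuracy (weighted-sum scale).
#' @return List with `treatment_id` (character vector) and `achieved` (the
#'   realized raw score).
#' @export
plant_mentions <- function(table, target) {
  ord <- sample.int(nrow(table))
  cur <- 0; sel <- character(0)
  for (j in ord) {
    s <- table$weighted_score[j]
    if (abs(cur + s - target) < abs(cur - target)) {
      cur <- cur + s
      sel <- c(sel, table$treatment_id[j])
    }
  }
  list(treatment_id = sel, achieved = cur)
}

#' Simulate paired accuracy scores for a cohort
#'
#' Per profile, a latent accuracy target is drawn; the AI arm's target is
#' shifted by `delta`. Each arm's realized accuracy is the weighted sum of a
#' planted mention set (see [plant_mentions()]).
#'
#' @param table Consolidated guideline table.
#' @param n Number of profiles.
#' @param delta AI-minus-clinician shift of the latent target.
#' @param base_mean,base_sd Latent target distribution for the clinician arm.
#' @param mentions Logical: also return the planted mention sets.
#' @return Data frame with columns `profile_id`, `acc_ai`, `acc_clin` (and
#'   attribute `mentions` when requested: a long data frame
#'   `doc_id, treatment_id, polarity`).
#' @export
simulate_accuracy_pairs <- function(table, n, delta, base_mean = 3.5,
                                    base_sd = 0.8, mentions = FALSE) {
  max_ach <- sum(pmax(table$weighted_score, 0))
  clip <- function(x) pmin(pmax(x, 0.5), max_ach - 0.25)
  base <- clip(stats::rnorm(n, base_mean, base_sd))
  acc_ai <- numeric(n); acc_clin <- numeric(n)
  men <- if (mentions) vector("list", 2L * n) else NULL
  for (i in seq_len(n)) {
    m_clin <- plant_mentions(table, clip(base[i]))
    m_ai <- plant_mentions(table, clip(base[i] + delta))
    acc_clin[i] <- m_clin$achieved; acc_ai[i] <- m_ai$achieved
    if (mentions) {
      men[[2L * i - 1L]] <- data.frame(
        doc_id = sprintf("P%03d-AI", i),
        treatment_id = m_ai$treatment_id,
        polarity = "ADVISED", stringsAsFactors = FALSE)
      men[[2L * i]] <- data.frame(
        doc_id = sprintf("P%03d-CLIN", i),
        treatment_id = m_clin$treatment_id,
        polarity = "ADVISED", stringsAsFactors = FALSE)
    }
  }
  out <- data.frame(profile_id = sprintf("P%03d", seq_len(n)),
                    acc_ai = acc_ai, acc_clin = acc_clin,
                    stringsAsFactors = FALSE)
  if (mentions) attr(out, "mentions") <- do.call(rbind, men)
  out
}

#' Split a rubric total into integer per-dimension points
#'
#' Proportional to the dimension maxima, rounded so the dimension points sum
#' to the rounded total; remainders go to the dimensions with the largest
#' fractional parts.
#'
#' @param total Total points in 0..100.
#' @param def Instrument definition.
#' @return Named integer vector of dimension points.
#' @keywords internal
split_total <- function(total, def) {
  total <- min(max(round(total), 0), def$total_max)
  share <- total * def$dimensions / def$total_max
  pts <- floor(share)
  rem <- total - sum(pts)
  if (rem > 0) {
    ord <- order(share - pts, decreasing = TRUE)
    pts[ord[seq_len(rem)]] <- pts[ord[seq_len(rem)]] + 1
  }
  pmin(pts, def$dimensions)
}

#' Simulate adjudicated paired rubric totals
#'
#' Draws latent per-arm truths, splits them into dimensions, simulates two
#' noisy raters (plus a third for flagged dimensions) and adjudicates,
#' returning the final paired totals — the full rubric pipeline in miniature.
#'
#' @param n Number of profiles.
#' @param instrument Instrument name.
#' @param mean_ai,mean_clin,sd_ai,sd_clin Latent truth distributions per arm.
#' @param rater_noise_sd,p_disagreement,threshold Rater model, see
#'   [simulate_raters()].
#' @return Data frame `profile_id, total_ai, total_clin`.
#' @export
simulate_rubric_pairs <- function(n, instrument, mean_ai, mean_clin,
                                  sd_ai, sd_clin, rater_noise_sd = 3,
                                  p_disagreement = 0.05, threshold = 10) {
  def <- instrument_definition(instrument)
  one_arm <- function(doc_id, mu, sdv) {
    truth <- score_sheet(doc_id, instrument, "TRUTH",
                         split_total(stats::rnorm(1, mu, sdv), def))
    rr <- simulate_raters(truth, rater_noise_sd, p_disagreement,
                          threshold = threshold)
    final_score(rr$r1, rr$r2, rr$r3, threshold = threshold)$total
  }
  total_ai <- numeric(n); total_clin <- numeric(n)
  for (i in seq_len(n)) {
    total_ai[i] <- one_arm(sprintf("P%03d-AI", i), mean_ai, sd_ai)
    total_clin[i] <- one_arm(sprintf("P%03d-CLIN", i), mean_clin, sd_clin)
  }
  data.frame(profile_id = sprintf("P%03d", seq_len(n)),
             total_ai = total_ai, total_clin = total_clin,
             stringsAsFactors = FALSE)
}

#' Study-shaped cohort configuration
#'
#' Defaults mirror the study shape: 50 patient profiles, two arms, two
#' primary raters plus a third for adjudication, a 10-point disagreement
#' threshold, and arm-level effects on efficiency, readability, accuracy and
#' rubric scores set to the magnitudes the evaluation is designed to detect.
#'
#' @param n_profiles Number of patient profiles (pairs), default 50.
#' @param seed Master seed; all components draw from named substreams
#'   derived from it.
#' @param fk_target,fk_sd Per-arm Flesch-Kincaid grade targets (named
#'   `AI`, `CLIN`).
#' @param sentences_range,words_per_sentence_range Integer ranges for
#'   document shape.
#' @param wpm_median,wpm_log_sd Per-arm lognormal words-per-minute model.
#' @param accuracy_base_mean,accuracy_base_sd,accuracy_delta Accuracy target
#'   model on the raw weighted-sum scale.
#' @param rubric_mean,rubric_sd Per-instrument, per-arm latent truth means
#'   and SDs (named lists).
#' @param rater_noise_sd,p_disagreement,threshold Rater simulation model.
#' @param n_treatments Size of the generated guideline table.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_profiles = 50, seed = 1,
                          fk_target = c(AI = 11.56, CLIN = 12.67),
                          fk_sd = c(AI = 1.08, CLIN = 0.95),
                          sentences_range = c(30L, 45L),
                          words_per_sentence_range = c(12L, 18L),
                          wpm_median = c(AI = 530.03, CLIN = 37.29),
                          wpm_log_sd = c(AI = 0.14, CLIN = 0.08),
                          accuracy_base_mean = 3.5,
                          accuracy_base_sd = 0.8,
                          accuracy_delta = 0.55,
                          rubric_mean = list(
                            PERSONALIZATION = c(AI = 54.32, CLIN = 33.20),
                            COMPREHENSIVENESS = c(AI = 51.74, CLIN = 35.26),
                            SAFETY = c(AI = 61, CLIN = 50)),
                          rubric_sd = list(
                            PERSONALIZATION = c(AI = 6.21, CLIN = 5.40),
                            COMPREHENSIVENESS = c(AI = 6.47, CLIN = 6.66),
                            SAFETY = c(AI = 6, CLIN = 6)),
                          rater_noise_sd = 3, p_disagreement = 0.05,
                          threshold = 10, n_treatments = 12) {
  cfg <- list(n_profiles = as.integer(n_profiles), seed = as.integer(seed),
              fk_target = fk_target, fk_sd = fk_sd,
              sentences_range = as.integer(sentences_range),
              words_per_sentence_range = as.integer(words_per_sentence_range),
              wpm_median = wpm_median, wpm_log_sd = wpm_log_sd,
              accuracy_base_mean = accuracy_base_mean,
              accuracy_base_sd = accuracy_base_sd,
              accuracy_delta = accuracy_delta,
              rubric_mean = rubric_mean, rubric_sd = rubric_sd,
              rater_noise_sd = rater_noise_sd,
              p_disagreement = p_disagreement,
              threshold = threshold, n_treatments = as.integer(n_treatments))
  if (cfg$n_profiles < 2L) stop("n_profiles must be >= 2", call. = FALSE)
  if (cfg$rater_noise_sd < 0) stop("rater_noise_sd must be >= 0", call. = FALSE)
  if (cfg$p_disagreement < 0 || cfg$p_disagreement > 1) {
    stop("p_disagreement must be in [0, 1]", call. = FALSE)
  }
  class(cfg) <- "cohort_config"
  cfg
}

# named RNG substreams derived from the master seed
substream_seed <- function(seed, name) {
  offsets <- c(text = 1L, table = 2L, raters = 3L, timing = 4L,
               mentions = 5L, blinding = 6L)
  (as.integer(seed) * 977L + offsets[[name]] * 10007L) %% 2147483587L
}

#' Generate a complete synthetic study cohort
#'
#' Produces `n_profiles` paired documents (AI and clinician arm) with exact
#' token ledgers, authoring times realizing the configured words-per-minute
#' medians, a guideline table, planted mention sets realizing the configured
#' accuracy targets, and three-rater rubric score files. Fully reproducible
#' from the config seed.
#'
#' @param config A [cohort_config()].
#' @return List with `documents` (data frame: doc_id, profile_id, arm, text,
#'   authoring_minutes), `ledgers` (named list of `token_stats`),
#'   `guidelines`, `mentions`, `ratings` (long format) and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_profiles
  bank <- word_bank()
  max_syl <- max(bank$syllables)

  guidelines <- generate_guideline_table(config$n_treatments,
                                         seed = substream_seed(config$seed, "table"))

  # documents + ledgers
  set.seed(substream_seed(config$seed, "text"))
  docs <- vector("list", 2L * n); ledgers <- vector("list", 2L * n)
  ids <- character(2L * n)
  k <- 0L
  for (i in seq_len(n)) {
    for (arm in c("AI", "CLIN")) {
      k <- k + 1L
      S <- sample(config$sentences_range[1L]:config$sentences_range[2L], 1L)
      wps <- sample(config$words_per_sentence_range[1L]:
                      config$words_per_sentence_range[2L], 1L)
      fk_t <- stats::rnorm(1, config$fk_target[[arm]], config$fk_sd[[arm]])
      spw <- (fk_t + 15.59 - 0.39 * wps) / 11.8
      spw <- min(max(spw, 1.05), max_syl - 0.5)
      g <- generate_text(S, wps, spw, bank)
      ids[k] <- sprintf("P%03d-%s", i, arm)
      docs[[k]] <- data.frame(doc_id = ids[k],
                              profile_id = sprintf("P%03d", i), arm = arm,
                              text = g$text, authoring_minutes = NA_real_,
                              stringsAsFactors = FALSE)
      ledgers[[k]] <- g$stats
    }
  }
  documents <- do.call(rbind, docs)
  names(ledgers) <- ids

  # authoring minutes realizing the per-arm WPM model
  set.seed(substream_seed(config$seed, "timing"))
  for (k in seq_len(nrow(documents))) {
    arm <- documents$arm[k]
    wpm <- config$wpm_median[[arm]] *
      exp(stats::rnorm(1, 0, config$wpm_log_sd[[arm]]))
    documents$authoring_minutes[k] <- ledgers[[k]]$n_words / wpm
  }

  # planted mentions realizing the accuracy targets
  set.seed(substream_seed(config$seed, "mentions"))
  acc <- simulate_accuracy_pairs(guidelines, n, config$accuracy_delta,
                                 config$accuracy_base_mean,
                                 config$accuracy_base_sd, mentions = TRUE)
  mentions <- attr(acc, "mentions")

  # three-rater rubric scores
  set.seed(substream_seed(config$seed, "raters"))
  rat <- list(); r_i <- 0L
  for (i in seq_len(n)) {
    for (arm in c("AI", "CLIN")) {
      doc_id <- sprintf("P%03d-%s", i, arm)
      for (inst in c("PERSONALIZATION", "COMPREHENSIVENESS", "SAFETY")) {
        def <- instrument_definition(inst)
        mu <- config$rubric_mean[[inst]][[arm]]
        sdv <- config$rubric_sd[[inst]][[arm]]
        truth <- score_sheet(doc_id, inst, "TRUTH",
                             split_total(stats::rnorm(1, mu, sdv), def))
        rr <- simulate_raters(truth, config$rater_noise_sd,
                              config$p_disagreement,
                              threshold = config$threshold)
        for (r in rr) {
          r_i <- r_i + 1L
          rat[[r_i]] <- data.frame(doc_id = doc_id, instrument = inst,
                                   rater_id = r$rater_id,
                                   dimension = names(r$points),
                                   points = as.integer(unname(r$points)),
                                   stringsAsFactors = FALSE)
        }
      }
    }
  }
  ratings <- do.call(rbind, rat)
  rownames(ratings) <- NULL

  list(documents = documents, ledgers = ledgers, guidelines = guidelines,
       mentions = mentions, ratings = ratings, config = config)
}

#' Write a generated cohort to disk in the pipeline's file formats
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (docs.jsonl, guidelines.csv,
#'   mentions.csv, ratings.csv).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(docs = file.path(dir, "docs.jsonl"),
             guidelines = file.path(dir, "guidelines.csv"),
             mentions = file.path(dir, "mentions.csv"),
             ratings = file.path(dir, "ratings.csv"))
  write_docs_jsonl(cohort$documents, paths[["docs"]])
  utils::write.csv(cohort$guidelines, paths[["guidelines"]], row.names = FALSE)
  utils::write.csv(cohort$mentions, paths[["mentions"]], row.names = FALSE)
  utils::write.csv(cohort$ratings, paths[["ratings"]], row.names = FALSE)
  invisible(paths)
}
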