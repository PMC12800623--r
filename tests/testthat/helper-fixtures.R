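# Shared fixtures, built once per test run and cached across test files.
.fixtures <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

test_events <- function() cached("events", function() ebm_events())

# default study-condition cohort with longitudinal visits
shared_cohort <- function() {
  cached("cohort", function() {
    cfg <- cohort_config(n_patients = 300, seed = 7)
    generate_longitudinal(cfg, generate_cohort(cfg))
  })
}

shared_wscores <- function() {
  cached("wscores", function() {
    co <- shared_cohort()
    nm <- fit_normative_model(co$volumes)
    compute_wscores(nm, co$volumes)
  })
}

# baseline-trained single-subtype model on the shared cohort
shared_model <- function() {
  cached("model", function() {
    ws <- shared_wscores()
    pat <- ws[ws$group == "SCA3" & ws$visit_index == 1, ]
    z <- severity_matrix(pat)
    fit_subtypes(z, test_events(), k = 1,
                 control = ebm_control(profile = "test"), seed = 1)
  })
}

shared_baseline_stages <- function() {
  cached("stages", function() {
    ws <- shared_wscores()
    pat <- ws[ws$group == "SCA3" & ws$visit_index == 1, ]
    st <- assign_stages(shared_model(), severity_matrix(pat))
    data.frame(subject_id = pat$subject_id, stage = st$map_stage)
  })
}

# per-visit staged table for longitudinal analyses
shared_stage_table <- function() {
  cached("stage_table", function() {
    co <- shared_cohort()
    ws <- shared_wscores()
    pat <- ws[ws$group == "SCA3", ]
    st <- assign_stages(shared_model(), severity_matrix(pat))
    vol <- co$volumes[co$volumes$group == "SCA3", ]
    stopifnot(identical(paste(pat$subject_id, pat$visit_index),
                        paste(vol$subject_id, vol$visit_index)))
    cl1 <- co$clinical[co$clinical$visit_index == 1, ]
    data.frame(subject_id = pat$subject_id, visit_index = pat$visit_index,
               time = vol$time, stage = st$map_stage,
               ataxia_status = cl1$ataxia_status[match(pat$subject_id,
                                                       cl1$subject_id)],
               stringsAsFactors = FALSE)
  })
}

# severities drawn directly from the model's generative process
direct_severities <- function(n, seed, sequence = NULL, noise_sd = 1,
                              events = test_events(),
                              stage_probs = cohort_config()$stage_distribution) {
  set.seed(seed)
  if (is.null(sequence)) sequence <- default_true_sequence(events)
  N <- events$n_events
  stages <- sample(0:N, n, replace = TRUE, prob = stage_probs)
  G <- expected_trajectory(sequence, events)
  z <- G[stages + 1, , drop = FALSE] +
    matrix(rnorm(n * length(events$biomarkers), 0, noise_sd), n)
  list(z = z, stages = stages, sequence = sequence)
}

# reversed (and re-canonicalized) variant of a sequence, for subtype fixtures
reversed_sequence <- function(sequence, events = test_events()) {
  atrostage:::canonicalize_sequence(rev(sequence), events)
}

# slow R-loop reference for the stage-marginalised sequence likelihood
reference_log_likelihood <- function(z, sequence, events, sigma = 1,
                                     z_max = 5) {
  N <- events$n_events
  G <- expected_trajectory(sequence, events, z_max = z_max)
  total <- 0
  for (i in seq_len(nrow(z))) {
    stage_lik <- numeric(N + 1)
    for (s in 0:N) {
      ll <- 0
      for (b in seq_along(events$biomarkers)) {
        if (is.na(z[i, b])) next
        ll <- ll + dnorm(z[i, b], G[s + 1, b], sigma, log = TRUE)
      }
      stage_lik[s + 1] <- ll
    }
    total <- total + log(mean(exp(stage_lik - max(stage_lik)))) +
      max(stage_lik)
  }
  total
}

# all valid sequences for tiny event spaces, by filtering permutations
all_valid_sequences <- function(events) {
  N <- events$n_events
  perms <- as.matrix(expand.grid(rep(list(seq_len(N)), N)))
  perms <- perms[apply(perms, 1, function(p) !anyDuplicated(p)), ,
                 drop = FALSE]
  keep <- apply(perms, 1, function(p) is_valid_sequence(p, events))
  perms[keep, , drop = FALSE]
}
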