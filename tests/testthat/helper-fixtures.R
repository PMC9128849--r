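# Shared fixtures, built in code.

# random valid D x C / confidence draws
rand_dxc <- function(n) sample(c(-4:-1, 1:4), n, replace = TRUE)
rand_conf <- function(n) sample(1:4, n, replace = TRUE)

# a tiny image-pair table for design plans
tiny_pairs <- function(n = 40) {
  data.frame(pair_id = sprintf("pair%03d", seq_len(n)),
             critical_location = rep(1:9, length.out = n),
             stringsAsFactors = FALSE)
}

# hand-built response table: one participant, one pair, explicit rows
make_responses <- function(patch_type, dxc,
                           congruence = "congruent",
                           participant = "P001", pair = "pairA",
                           location = 5L) {
  n <- length(dxc)
  patch_type <- rep(patch_type, length.out = n)
  congruence <- rep(congruence, length.out = n)
  location <- rep(location, length.out = n)
  data.frame(
    participant_id = rep(participant, length.out = n),
    experiment = "exp1",
    trial_index = seq_len(n),
    image_pair_id = rep(pair, length.out = n),
    initial_congruence = congruence,
    probe_index = 1L,
    patch_type = patch_type,
    location = location,
    eccentricity_class = eccentricity_class(location),
    decision = ifelse(dxc > 0, "yes", "no"),
    confidence = abs(dxc),
    dxc = dxc,
    is_catch = FALSE,
    catch_correct = NA,
    stringsAsFactors = FALSE
  )
}
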