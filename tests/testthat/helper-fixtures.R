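# Shared fixture builders; all randomness is seeded by the caller.

random_contact_counts <- function(n, lambda = 50) {
  m <- matrix(rpois(n * n, lambda), n, n)
  m <- m + t(m)
  diag(m) <- 0
  m
}

small_panel <- function(seed = 1, ...) {
  simulate_panel(simulation_config(seed = seed, ...))
}

# Extract per-organ state-track panels from a simulated panel.
panel_organ_states <- function(panel, states = truth_states(panel)) {
  ct <- panel$cell_types
  orgs <- panel$config$secondary_organs
  organ_panels <- lapply(orgs, function(org) {
    list(normal = states[[paste0(org, "_normal")]],
         cancers = states[ct$name[ct$organ == org & ct$status == "localized"]])
  })
  names(organ_panels) <- orgs
  list(
    primary_normal = states[[paste0(panel$config$primary_organ, "_normal")]],
    localized = states[ct$name[ct$organ == panel$config$primary_organ &
                                 ct$status == "localized"]],
    metastatic = states[ct$name[ct$organ == panel$config$primary_organ &
                                  ct$status == "metastatic"]],
    organ_panels = organ_panels
  )
}
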