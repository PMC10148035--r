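## Build a synthetic trajectory with prescribed constant species profiles.
## profiles: named list species -> length-N vector (constant in time).
synthetic_trajectory <- function(profiles, N = 10, times = 0:10,
                                 l = 0.2, T_ini = 25) {
  species <- species_catalog()$name
  conc <- array(0, dim = c(length(species), N, length(times)),
                dimnames = list(species, NULL, NULL))
  for (nm in names(profiles)) conc[nm, , ] <- profiles[[nm]]
  ev <- cycle_event_state()
  ev$T_ini <- T_ini
  structure(list(times = times, conc = conc, l = rep(l, length(times)),
                 events = ev, N = N, species = species,
                 root_time = NA_real_),
            class = "caulo_trajectory")
}

## Parameter table with a chosen subset of rates; everything else zeroed.
## Keeps structural constants (exponents, eps, diffusivity law) intact.
zeroed_params <- function(keep = c()) {
  p <- default_parameters()
  rates <- grepl("^k_", p$name) | p$name %in% c("mu", "alpha_PopZPodJ",
    "alpha_PodJSpmX", "alpha_SpmXPopZ", "alpha_SpmXPodJ", "alpha_DivLPodJ")
  z <- setdiff(p$name[rates], names(keep))
  p$value[match(z, p$name)] <- 0
  p$lower[match(z, p$name)] <- 0
  if (length(keep)) p <- set_params(p, keep)
  p
}
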