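# Shared fixtures: every object is built in code at test time.

des_params <- function() kinetic_preset("table1_desensitizable")
nondes_params <- function() kinetic_preset("table1_nondesensitizable")

single_env <- function(L_max = 17.6) {
  ligand_environment(power_field("L", c(0, 0), L_max = L_max))
}

opposing_env <- function() {
  ligand_environment(power_field("L1", c(-500, 0)),
                     power_field("L2", c(500, 0)))
}

final_pos <- function(track) {
  c(track$x_um[nrow(track)], track$y_um[nrow(track)])
}

dist_to <- function(p, q) sqrt(sum((p - q)^2))

track_of <- function(cohort, id) cohort[cohort$track_id == id, ]

# short migration settings for unit tests
short_config <- function(total_time = 5, seed = 42L, ...) {
  migration_config(total_time = total_time, seed = seed, ...)
}
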