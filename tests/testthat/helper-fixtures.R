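# Shared fixtures: typical extensive-metabolizer parameter sets and small
# builders used across the suite.

em_pk <- function() oral_pk_parameters(v_over_f = 1.12, k01 = 2, k10 = 0.277,
                                       tlag = 0.5)

em_pd <- function(endpoint) {
  switch(endpoint,
    body_temperature = indirect_response_parameters(41.30, 1.04, 0.04,
                                                    193.2, 5.09),
    creeping_speed = indirect_response_parameters(0.90, 0.95, 0.71,
                                                  239.4, 4.74),
    vertical_force = indirect_response_parameters(0.09, 7.40, 0.98,
                                                  160.8, 6.13),
    lameness_score = indirect_response_parameters(5.34, 1.08, 1,
                                                  284.3, 4.25),
    stop("no fixture for ", endpoint))
}

modeled_endpoints <- c("body_temperature", "creeping_speed",
                       "vertical_force", "lameness_score")

oral_profile_from <- function(params, dose = 2,
                              times = c(0.5, 1, 1.5, 4, 6, 9, 15, 30, 48),
                              id = "d1") {
  conc <- oral_concentration(params, dose, times)
  concentration_profile(id, "oral", dose, times, conc,
                        bql_flags = rep(FALSE, length(times)))
}

pd_times <- function() c(0, 2, 4, 9, 15, 22, 27)
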