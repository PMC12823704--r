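# toy fixtures built in code: constant-rate event tables, flat life tables,
# and an exhaustive path-enumeration oracle for the cohort engine

const_rates <- function(cf = 0, cn = 0, vf = 0, vn = 0, of = 0) {
  do.call(rbind, lapply(c("female", "male"), function(sx)
    data.frame(sex = sx, age = 25:99, p_chd_fatal = cf, p_chd_nonfatal = cn,
               p_cve_fatal = vf, p_cve_nonfatal = vn, p_other_death = of)))
}

flat_life_table <- function(q = 0.01, f_chd = 0.2, f_cve = 0.1) {
  validate_life_table(do.call(rbind, lapply(c("female", "male"), function(sx)
    data.frame(sex = sx, age = 25:99, q_all = q, f_chd = f_chd,
               f_cve = f_cve))))
}

# exhaustive enumeration of all state paths over a few cycles, using only
# cycle_transitions(); independent of the matrix propagation in run_cohort
enumerate_paths <- function(rates, sex, start_age, n_cycles,
                            mult = history_multipliers()) {
  living <- c("event_free", "post_chd", "post_cve", "post_both")
  states <- c(living, "dead_chd", "dead_cve", "dead_other")
  m <- rates[rates$sex == sex, ]
  occ <- matrix(0, nrow = n_cycles + 1L, ncol = 7L,
                dimnames = list(NULL, states))
  occ[1L, "event_free"] <- 1
  cum_first <- numeric(n_cycles)
  recurse <- function(state, prob, t, had_event) {
    if (prob == 0) return()
    if (t > n_cycles) return()
    p <- m[m$age == start_age + t - 1L,
           c("p_chd_fatal", "p_chd_nonfatal", "p_cve_fatal",
             "p_cve_nonfatal", "p_other_death")]
    if (state %in% living) {
      tr <- cycle_transitions(p, state, mult)
      for (s2 in states) {
        pr <- prob * tr[[s2]]
        if (pr == 0) next
        occ[t + 1L, s2] <<- occ[t + 1L, s2] + pr
        first <- !had_event && state == "event_free" &&
          s2 != "event_free" && s2 != "dead_other"
        if (first) cum_first[t] <<- cum_first[t] + pr
        recurse(s2, pr, t + 1L, had_event || first)
      }
    } else {
      occ[t + 1L, state] <<- occ[t + 1L, state] + prob
      recurse(state, prob, t + 1L, had_event)
    }
  }
  recurse("event_free", 1, 1L, FALSE)
  list(dist = occ, cum_first_event = cumsum(cum_first))
}
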