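# Shared fixtures, built in code at test time.

tetrahedron_mesh <- function() {
  trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
          rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)))
}

# Rodrigues rotation about a random axis.
random_rotation <- function() {
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, pi)
  K <- matrix(c(0, -ax[3], ax[2],
                ax[3], 0, -ax[1],
                -ax[2], ax[1], 0), 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

random_rigid <- function() {
  rigid_transform(random_rotation(), rnorm(3, 0, 30))
}

# Expensive shared objects (the validation cohort and precision tables) are
# built once per test run, on first use.
.test_cache <- new.env(parent = emptyenv())

cache_get <- function(name, builder) {
  if (is.null(.test_cache[[name]])) .test_cache[[name]] <- builder()
  .test_cache[[name]]
}

validation_cohort <- function() {
  cache_get("cohort", function() generate_cohort(cohort_spec(n = 20, seed = 101)))
}

validation_measurements <- function() {
  cache_get("measurements", function() {
    co <- validation_cohort()
    lapply(co$heads, function(h) measure_all(h$head))
  })
}

validation_measurement_table <- function() {
  cache_get("mtable", function() {
    ms <- validation_measurements()
    do.call(rbind, lapply(seq_along(ms), function(i)
      measurement_row(ms[[i]], subject = i)))
  })
}

automatic_precision <- function() {
  cache_get("auto_precision", function() {
    reps <- simulate_repeated_scans(head_spec(noise_sd = 0.1), n_repeats = 8,
                                    seed = 500)
    vals <- lapply(reps, function(r) {
      m <- measure_all(r$head)
      c(length = m$left$length, width = m$left$width,
        protrusion = m$left$protrusion, acangle = m$left$acangle,
        inclination = m$left$inclination,
        si_position = m$bilateral$superoinferior_diff,
        pa_position = m$bilateral$posteroanterior_diff)
    })
    precision_from_repeats(as.data.frame(do.call(rbind, vals)),
                           method = "automatic")
  })
}

manual_precision <- function() {
  cache_get("manual_precision", function() {
    gh <- generate_head(head_spec(noise_sd = 0))
    manual_precision_from_landmarks(gh$head$landmarks$left,
                                    observer_sd = 1.5, n_rep = 300,
                                    seed = 77)
  })
}
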