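aq <- function(gill, flow = 1, volume = 2, genus = "Alviniconcha") {
  aquarium_config("aq1", "experimental", flow, volume, gill, genus = genus)
}

test_that("net rate is the control-differenced, flow-scaled, mass-normalized flux", {
  # hand oracle: (5.7 - 66) * 1.0 / 22.56
  r <- net_rate(conc_row("aq1", "sulfide", 1, 5.7),
                conc_row("control", "sulfide", 1, 66), aq(22.56))
  expect_equal(r$rate_umol_g_h, -2.673, tolerance = 5e-4)
  expect_equal(r$flag, "ok")
  expect_equal(r$reference_channel, "control")

  # no difference, no flux
  r0 <- net_rate(conc_row("aq1", "sulfide", 1, 66),
                 conc_row("control", "sulfide", 1, 66), aq(22.56))
  expect_equal(r0$rate_umol_g_h, 0)

  # excretion: effluent above a below-detection reference is positive
  re <- net_rate(conc_row("aq1", "thiosulfate", 1, 73),
                 conc_row("input", "thiosulfate", 1, 10, is_bdl = TRUE),
                 aq(36.85, flow = 0.5))
  expect_equal(re$rate_umol_g_h, 0.990, tolerance = 1e-3)
  expect_gt(re$rate_umol_g_h, 0)
  expect_equal(re$flag, "bdl")
})

test_that("net rate validates its pairing and normalization", {
  expect_error(net_rate(conc_row("aq1", "sulfide", 1, 5),
                        conc_row("control", "thiosulfate", 1, 5), aq(10)),
               "different analytes")
  expect_error(net_rate(conc_row("aq1", "sulfide", 1, 5),
                        conc_row("control", "sulfide", 2, 5), aq(10)),
               "different sets")
  expect_error(net_rate(conc_row("aq1", "sulfide", 1, 5),
                        conc_row("control", "sulfide", 1, 6),
                        aquarium_config("aq1", "experimental", 1, 2, 0)),
               "total_gill_wet_g")
})

test_that("rates are antisymmetric in the pair and linear in flow and difference", {
  set.seed(21)
  for (i in 1:20) {
    e <- conc_row("aq1", "sulfide", 1, runif(1, 0, 300))
    r <- conc_row("control", "sulfide", 1, runif(1, 0, 300))
    flow <- runif(1, 0.2, 3)
    gill <- runif(1, 5, 50)
    a1 <- aq(gill, flow = flow)
    fwd <- net_rate(e, r, a1)$rate_umol_g_h
    rev <- net_rate(r, e, a1)$rate_umol_g_h
    expect_equal(fwd, -rev)
    expect_equal(net_rate(e, r, aq(gill, flow = 2 * flow))$rate_umol_g_h,
                 2 * fwd, tolerance = 1e-12)
    expect_equal(fwd, (e$mean_uM - r$mean_uM) * flow / gill, tolerance = 1e-12)
  }
})

test_that("the gating cutoff is the later of the time and turnover bounds", {
  pol <- gating_policy()
  expect_equal(gating_cutoff_h(aq(10, flow = 1, volume = 2), pol), 10)
  expect_equal(gating_cutoff_h(aq(10, flow = 1, volume = 8), pol), 24)

  conc <- dplyr::bind_rows(
    conc_row("aq1", "sulfide", 1, 5, start_s = 2 * 3600),
    conc_row("aq1", "sulfide", 6, 5, start_s = 12 * 3600))
  gated <- gate_sets(conc, aq(10, flow = 1, volume = 2), pol)
  expect_equal(gated$cutoff_h, 10)
  expect_equal(nrow(gated$intervals), 1L)
  expect_equal(gated$intervals$start_s, 12 * 3600)

  expect_warning(gate_sets(conc[1, ], aq(10, 1, 2), pol), "cutoff")
})

test_that("rate summaries give per-genus mean, sd and range over sets", {
  rates <- dplyr::bind_rows(
    net_rate(conc_row("aq1", "sulfide", 1, 3), conc_row("c", "sulfide", 1, 73),
             aq(10)),
    net_rate(conc_row("aq1", "sulfide", 2, 7), conc_row("c", "sulfide", 2, 73),
             aq(10)))
  # rates are -7.0 and -6.6: two-point closed forms
  s <- summarize_rates(rates)
  expect_equal(s$mean_rate, -6.8)
  expect_equal(s$sd_rate, sqrt(0.08), tolerance = 1e-9)
  expect_equal(s$min_rate, -7.0)
  expect_equal(s$max_rate, -6.6)
  expect_equal(s$n_sets, 2L)
  expect_equal(s$direction, "uptake")

  s1 <- summarize_rates(rates[1, ])
  expect_equal(s1$sd_rate, 0)
  expect_true(s1$single_set)

  const <- dplyr::bind_rows(rates[1, ], rates[1, ], rates[1, ])
  expect_equal(summarize_rates(const)$sd_rate, 0)

  both_bdl <- rates[1, ]
  both_bdl$flag <- "bdl_pair"
  expect_error(summarize_rates(both_bdl), "below detection")
})

test_that("set pairing matches each experimental interval to its own set's reference", {
  conc <- dplyr::bind_rows(
    conc_row("aq1", "sulfide", 1, 10), conc_row("ref", "sulfide", 1, 100),
    conc_row("aq1", "sulfide", 2, 20), conc_row("ref", "sulfide", 2, 90),
    conc_row("aq1", "sulfide", 3, 30)) # set 3 lacks a reference: dropped
  aqs <- dplyr::bind_rows(aq(10), aquarium_config("ref", "control", 1, 2, 0))
  rates <- set_rates(conc, aqs, "ref")
  expect_equal(nrow(rates), 2L)
  expect_equal(rates$rate_umol_g_h, c(-9, -7))
  expect_error(set_rates(conc, aqs, "nope"), "absent")
})

test_that("control-referenced and input-referenced modes agree when control equals input", {
  input_c <- 120
  conc <- dplyr::bind_rows(
    conc_row("aq1", "sulfide", 1, 40),
    conc_row("control", "sulfide", 1, input_c),
    conc_row("input", "sulfide", 1, input_c))
  aqs <- dplyr::bind_rows(
    aq(12),
    aquarium_config("control", "control", 1, 2, 0),
    aquarium_config("input", "input", 1, 2, 0))
  r_ctrl <- set_rates(conc[conc$channel != "input", ], aqs, "control")
  r_input <- set_rates(conc[conc$channel != "control", ], aqs, "input")
  expect_equal(r_ctrl$rate_umol_g_h, r_input$rate_umol_g_h)
})

test_that("steady-state mass balance is recovered exactly from noiseless scans", {
  # aquarium removing 250 umol/h at 1 L/h from 349 uM input: effluent 99 uM
  sched <- set_schedule(c("aq1", "b", "c", "control"))
  conc <- c(aq1 = steady_state_effluent(349, 250, 1), b = 349, c = 349,
            control = 349)
  expect_equal(unname(conc[["aq1"]]), 99)
  scans <- cycle_scans(sched$channels, conc, n_hours = 12)
  ints <- assemble_intervals(scans, sched)
  cc <- interval_concentrations(ints)
  aqs <- dplyr::bind_rows(
    aquarium_config("aq1", "experimental", 1, 2, 25, genus = "Alviniconcha"),
    aquarium_config("b", "experimental", 1, 2, 1),
    aquarium_config("c", "experimental", 1, 2, 1),
    aquarium_config("control", "control", 1, 2, 0))
  rates <- set_rates(cc[cc$channel %in% c("aq1", "control"), ], aqs, "control")
  recovered_total <- -mean(rates$rate_umol_g_h) * 25
  expect_equal(recovered_total, 250, tolerance = 1e-9)
})

test_that("sustained excretion needs consecutive above-detection sets", {
  mk <- function(set, exp_bdl, ref_bdl) dplyr::bind_rows(
    conc_row("aq1", "thiosulfate", set, 50, is_bdl = exp_bdl),
    conc_row("ref", "thiosulfate", set, 5, is_bdl = ref_bdl))
  sustained <- dplyr::bind_rows(mk(1, FALSE, TRUE), mk(2, FALSE, TRUE),
                                mk(3, FALSE, TRUE))
  out <- sustained_excretion(sustained, "ref")
  expect_true(out$sustained)
  expect_equal(out$n_consecutive, 3L)

  sporadic <- dplyr::bind_rows(mk(1, FALSE, TRUE), mk(2, TRUE, TRUE),
                               mk(3, FALSE, TRUE))
  expect_false(sustained_excretion(sporadic, "ref")$sustained)

  # compound present in the reference too: not excretion
  in_ref <- dplyr::bind_rows(mk(1, FALSE, FALSE), mk(2, FALSE, FALSE))
  expect_false(sustained_excretion(in_ref, "ref")$sustained)
})
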