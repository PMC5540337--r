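test_that("appearance rates and their per-area activity ratios", {
  expect_equal(appearance_rate("FA1"), 72.3)
  expect_equal(appearance_rate("FA2_LOW"), 9.5)
  expect_equal(appearance_rate("FA2_HIGH"), 1.5)
  expect_equal(appearance_rate("FA3"), 0.3)
  # underlying activity counts 14450:1900:300:60 scale as ~250:33:5:1
  act <- c(14450, 1900, 300, 60)
  expect_equal(act / act[4], c(240.8, 31.7, 5, 1), tolerance = 0.01)
  expect_error(appearance_rate("FA9"), "unknown functional area")
})

test_that("encounter probability is linear in perimeter + area, clamped to [0,1]", {
  expect_equal(encounter_probability(1200, 90000), 0.8208)
  expect_equal(encounter_probability(0, 0), 0)
  expect_equal(encounter_probability(740, 21000), 9e-6 * 21740)
  expect_equal(encounter_probability(1e6, 1e8), 1)  # clamp
  m <- rectangle_metrics(300, 70)
  expect_equal(encounter_probability(m), 0.19566)
})

test_that("passage probability: threshold, log-linear mid-range, clamp at 1", {
  expect_equal(passage_probability(5, "side"), 0)
  expect_equal(passage_probability(0, "roof"), 0)
  expect_equal(passage_probability(30, "roof"), 0.34 * log(30) - 0.55)
  expect_equal(passage_probability(30, "side"), 0.30 * log(30) - 0.52)
  expect_equal(passage_probability(307, "side"), 1)   # 1.198 pre-clamp
  expect_equal(passage_probability(500, "roof"), 1)
  # passage fits imply impassability near 5 mm: exp(-intercept/slope)
  expect_equal(exp(0.55 / 0.34), 5.04, tolerance = 0.01)
  expect_equal(exp(0.52 / 0.30), 5.66, tolerance = 0.01)
})

test_that("roof premium: roof passage exceeds side passage off the clamp", {
  for (w in c(6, 10, 30, 60, 90)) {
    expect_gt(passage_probability(w, "roof"), passage_probability(w, "side"))
  }
})

test_that("per-hole entry rates reproduce the worked scenario holes", {
  roof_sq <- rect_hole("r", "FA1", 30, 30)
  expect_equal(hole_entry_rate(roof_sq)$entries_per_hour, 0.402481,
               tolerance = 1e-5)
  slit <- rect_hole("s", "FA2_LOW", 300, 70)
  expect_equal(hole_entry_rate(slit)$entries_per_hour, 1.402525,
               tolerance = 1e-5)
  # impassable hole scores zero whatever its extent
  narrow <- rect_hole("n", "FA2_LOW", 300, 5)
  expect_equal(hole_entry_rate(narrow)$entries_per_hour, 0)
})

test_that("whole-net assessment: totals, shares and the roof-only subset", {
  a <- assess_net(mixed_damage_net())
  expect_equal(a$total_entries_per_hour, 6.3009, tolerance = 1e-4)
  expect_equal(round(a$total_entries_per_hour, 1), 6.3)
  expect_equal(a$share_side, 0.8084, tolerance = 1e-3)
  expect_equal(sum(a$by_fa$share), 1)

  roof_only <- assess_net(lapply(1:3, function(i) {
    rect_hole(paste0("r", i), "FA1", 30, 30)
  }))
  expect_equal(roof_only$total_entries_per_hour, 1.2074, tolerance = 1e-4)

  empty <- assess_net(list())
  expect_equal(empty$total_entries_per_hour, 0)
  expect_true(is.na(empty$share_roof))
})

test_that("assessment total is additive over any partition of the holes", {
  holes <- mixed_damage_net()
  whole <- assess_net(holes)$total_entries_per_hour
  set.seed(11)
  idx <- sample(length(holes))
  cut <- 5
  part <- assess_net(holes[idx[1:cut]])$total_entries_per_hour +
    assess_net(holes[idx[-(1:cut)]])$total_entries_per_hour
  expect_equal(part, whole, tolerance = 1e-12)
})

test_that("risk scaling is linear and the identity at (1, 1)", {
  a <- assess_net(mixed_damage_net())
  expect_equal(scale_risk(a, 1, 1)$total_entries, a$total_entries_per_hour)
  expect_equal(scale_risk(a, 2, 3)$total_entries,
               6 * a$total_entries_per_hour)
  expect_equal(scale_risk(assess_net(list()), 5, 8)$total_entries, 0)
  expect_error(scale_risk(a, -1, 1), ">= 0")
})

test_that("identical holes rank FA1 > FA2_LOW > FA2_HIGH > FA3", {
  rates <- vapply(FA_LEVELS, function(fa) {
    hole_entry_rate(rect_hole("x", fa, 120, 40))$entries_per_hour
  }, numeric(1))
  expect_true(all(diff(rates) < 0))
})

test_that("entry rate is monotone in every hole dimension", {
  set.seed(23)
  for (rep in 1:30) {
    fa <- sample(FA_LEVELS, 1)
    w <- runif(1, 6, 200)
    l <- runif(1, w, 300)
    base <- hole_entry_rate(rect_hole("a", fa, l, w))$entries_per_hour
    wider <- hole_entry_rate(
      rect_hole("b", fa, max(l, w * 1.2), min(l, w * 1.2))
    )$entries_per_hour
    longer <- hole_entry_rate(
      rect_hole("c", fa, l * 1.2, w)
    )$entries_per_hour
    expect_gte(wider, base)
    expect_gte(longer, base)
  }
})

test_that("probabilities stay in [0,1] across extreme inputs", {
  set.seed(5)
  for (w in c(0, 1e-6, 5, 5 + 1e-12, 10^runif(5, 0, 4))) {
    for (side in c("roof", "side")) {
      p <- passage_probability(w, side)
      expect_gte(p, 0)
      expect_lte(p, 1)
    }
  }
  for (s in 10^runif(10, 0, 6)) {
    e <- encounter_probability(s, s^2)
    expect_gte(e, 0)
    expect_lte(e, 1)
  }
})

test_that("over-long rectangles split into equal, area-preserving pieces", {
  h <- rect_hole("long", "FA3", 400, 50)
  parts <- split_long_hole(h)
  expect_length(parts, 2)
  expect_equal(vapply(parts, function(p) p$shape$length, numeric(1)),
               c(200, 200))
  expect_equal(sum(vapply(parts, function(p) p$metrics$area, numeric(1))),
               400 * 50)

  at_cap <- rect_hole("cap", "FA3", 300, 50)
  expect_length(split_long_hole(at_cap), 1)

  h3 <- rect_hole("vlong", "FA2_LOW", 900, 20)
  parts3 <- split_long_hole(h3)
  expect_length(parts3, 3)
  expect_equal(sum(vapply(parts3, function(p) p$metrics$area, numeric(1))),
               900 * 20)

  big_circle <- circ_hole("c", "FA1", 400)
  expect_error(split_long_hole(big_circle), "apportion it manually")
})

test_that("equivalent diameters match the cross-area equal-risk solution", {
  target <- hole_entry_rate(circ_hole("ref", "FA1", 25))$entries_per_hour
  expect_equal(target, 0.20172, tolerance = 1e-4)
  expect_equal(equivalent_diameter(target, "FA2_LOW") / 10, 6.3,
               tolerance = 0.01)
  expect_equal(equivalent_diameter(target, "FA2_HIGH") / 10, 13.9,
               tolerance = 0.01)
  # FA3 solution sits on the passage clamp
  expect_equal(equivalent_diameter(target, "FA3") / 10, 30.64,
               tolerance = 0.01)
  # self-consistency: solving for a hole's own rate returns its diameter
  for (d in c(10, 40, 120)) {
    r <- hole_entry_rate(circ_hole("x", "FA2_HIGH", d))$entries_per_hour
    expect_equal(equivalent_diameter(r, "FA2_HIGH"), d, tolerance = 0.01)
  }
  expect_error(equivalent_diameter(100, "FA3", upper = 400), "no round hole")
})

test_that("side rectangles spanning FA boundaries are apportioned by band", {
  frags <- apportion_side_rectangle("h", 200, 100, 250)
  expect_length(frags, 2)
  expect_equal(vapply(frags, function(h) h$fa, character(1)),
               c("FA2_LOW", "FA2_HIGH"))
  areas <- vapply(frags, function(h) h$metrics$area, numeric(1))
  expect_equal(areas, c(200 * 50, 200 * 50))

  # tall hole crossing both cuts
  frags3 <- apportion_side_rectangle("t", 100, 500, 200)
  expect_equal(vapply(frags3, function(h) h$fa, character(1)),
               c("FA2_LOW", "FA2_HIGH", "FA3"))
  expect_equal(sum(vapply(frags3, function(h) h$metrics$area, numeric(1))),
               100 * 500)

  # fully inside one band: single fragment, fa from the height rule
  one <- apportion_side_rectangle("o", 100, 50, 700)
  expect_length(one, 1)
  expect_equal(one[[1]]$fa, "FA3")
})

test_that("roof location always maps to FA1 and custom params propagate", {
  h <- hole("r", "roof", hole_shape("circle", diameter = 30))
  expect_equal(h$fa, "FA1")
  slow <- an_gambiae_params(
    appearances_per_mosquito_hour = c(FA1 = 10, FA2_LOW = 9.5,
                                      FA2_HIGH = 1.5, FA3 = 0.3)
  )
  r <- hole_entry_rate(circ_hole("x", "FA1", 30, params = slow), slow)
  expect_equal(r$appearances_per_hour, 10)
})
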