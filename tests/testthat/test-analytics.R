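# three commodities with energy availabilities in ratio 2:3:5
three_food_avail <- function() {
  sys <- tiny_system()
  commodities <- dplyr::bind_rows(
    constant_series("c_x", "x", "cereals", 400, 200, 10),
    constant_series("c_y", "y", "fruits", 600, 300, 10),
    constant_series("c_z", "z", "pulses", 900, 500, 10)
  )
  food_types <- tibble::tibble(
    food_type_id = c("x_ft", "y_ft", "z_ft"),
    commodity_id = c("c_x", "c_y", "c_z"),
    share = 1, processing_yield = 1, inedible_fraction = 0
  )
  composition <- dplyr::bind_rows(
    composition_for("x_ft", c(energy = 100)),
    composition_for("y_ft", c(energy = 100)),
    composition_for("z_ft", c(energy = 100))
  )
  waste <- tibble::tibble(region_id = "r1",
                          food_group = c("cereals", "fruits", "pulses"),
                          fraction = 0, region_weight = 1)
  fs <- food_system(list(
    commodities = commodities, food_types = food_types,
    composition = composition,
    bioavailability = sys$bioavailability[0, ],
    waste = waste, demographics = sys$demographics, nrv = sys$nrv
  ))
  list(system = fs, avail = compute_availability(fs, 2018, 10))
}

test_that("contribution percentages follow the availability ratios", {
  tf <- three_food_avail()
  expect_equal(contribution_percent(tf$avail, "c_x", "energy"), 20)
  expect_equal(contribution_percent(tf$avail, "c_y", "energy"), 30)
  expect_equal(contribution_percent(tf$avail, "c_z", "energy"), 50)
  expect_equal(contribution_percent(tf$avail, c("c_x", "c_y", "c_z"),
                                    "energy"), 100)
  # single food supplying a nutrient owns 100% of it
  sys <- tiny_system()
  av <- compute_availability(sys, 2018, 10)
  expect_equal(contribution_percent(av, "milk", "fat"), 100)
  # zero total is undefined, reported NA with a warning
  expect_warning(p <- contribution_percent(tf$avail, "c_x", "fiber"), "zero")
  expect_true(is.na(p))
})

test_that("contribution ranking uses competition ranks with id tie-breaks", {
  tf <- three_food_avail()
  r <- rank_contributors(tf$avail, "energy")
  expect_equal(r$commodity_id, c("c_z", "c_y", "c_x"))
  expect_equal(r$rank, c(1, 2, 3))
  # engineered tie: x and y equal, z below
  sys <- tf$system
  sys$commodities$food_supply_kt[sys$commodities$commodity_id == "c_y"] <- 200
  sys$commodities$food_supply_kt[sys$commodities$commodity_id == "c_z"] <- 100
  av <- compute_availability(sys, 2018, 10)
  r2 <- rank_contributors(av, "energy")
  expect_equal(r2$commodity_id, c("c_x", "c_y", "c_z")) # tie broken by id
  expect_equal(r2$rank, c(1, 1, 3))                     # 1, 1, 3 pattern
})

test_that("ranking agrees with a brute-force sort oracle on random fixtures", {
  for (s in 1:50) {
    set.seed(s)
    vals <- round(stats::runif(6, 0, 10), 1) # rounding provokes ties
    ids <- sprintf("c%d", 1:6)
    # brute force: for each id count strictly greater values
    expected_rank <- vapply(vals, function(v) 1 + sum(vals > v), numeric(1))
    ord <- order(-vals, ids)
    r <- nutriflow:::competition_rank(vals[ord])
    expect_equal(r, expected_rank[ord])
    expect_equal(r[1], 1) # rank 1 holds the maximal value
  }
})

test_that("density is the edible-mass-weighted mean of food-type content", {
  sys <- tiny_system()
  commodities <- constant_series("c_w", "w", "cereals", 1000, 1000, 0)
  food_types <- tibble::tibble(
    food_type_id = c("w_ft1", "w_ft2"), commodity_id = "c_w",
    share = c(0.6, 0.4), processing_yield = 1, inedible_fraction = 0
  )
  composition <- dplyr::bind_rows(
    composition_for("w_ft1", c(calcium = 10)),
    composition_for("w_ft2", c(calcium = 20))
  )
  fs <- food_system(list(
    commodities = commodities, food_types = food_types,
    composition = composition, bioavailability = sys$bioavailability[0, ],
    waste = tibble::tibble(region_id = "r1", food_group = "cereals",
                           fraction = 0, region_weight = 1),
    demographics = sys$demographics, nrv = sys$nrv
  ))
  av <- compute_availability(fs, 2018, 10)
  d <- density_rank(fs$composition, fs$food_types, av$masses, "calcium")
  expect_equal(d$density, 0.6 * 10 + 0.4 * 20, tolerance = 1e-12)
  # one food type per commodity: density equals its composition value
  tf <- three_food_avail()
  d1 <- density_rank(tf$system$composition, tf$system$food_types,
                     tf$avail$masses, "energy")
  expect_true(all(d1$density == 100))
})

test_that("a dense low-mass food outranks in density while losing on contribution", {
  sys <- tiny_system()
  commodities <- dplyr::bind_rows(
    constant_series("bulk", "bulk", "cereals", 10000, 8000, 0),
    constant_series("seed", "seed", "nuts_seeds", 20, 10, 0)
  )
  food_types <- tibble::tibble(
    food_type_id = c("bulk_ft", "seed_ft"),
    commodity_id = c("bulk", "seed"),
    share = 1, processing_yield = 1, inedible_fraction = 0
  )
  composition <- dplyr::bind_rows(
    composition_for("bulk_ft", c(calcium = 30)),
    composition_for("seed_ft", c(calcium = 900))
  )
  fs <- food_system(list(
    commodities = commodities, food_types = food_types,
    composition = composition, bioavailability = sys$bioavailability[0, ],
    waste = tibble::tibble(region_id = "r1",
                           food_group = c("cereals", "nuts_seeds"),
                           fraction = 0, region_weight = 1),
    demographics = sys$demographics, nrv = sys$nrv
  ))
  av <- compute_availability(fs, 2018, 10)
  contrib <- rank_contributors(av, "calcium")
  dens <- density_rank(fs$composition, fs$food_types, av$masses, "calcium")
  expect_equal(contrib$commodity_id[contrib$rank == 1], "bulk")
  expect_equal(dens$commodity_id[dens$rank == 1], "seed")
})

test_that("waste share combines supply-chain losses and in-home waste", {
  # production 1000, losses 50; in-home waste configured to discard 20 kt
  sys <- tiny_system()
  commodities <- constant_series("c_w", "w", "cereals", 1000, 400, 50)
  food_types <- tibble::tibble(food_type_id = "w_ft", commodity_id = "c_w",
                               share = 1, processing_yield = 1,
                               inedible_fraction = 0)
  fs <- food_system(list(
    commodities = commodities, food_types = food_types,
    composition = composition_for("w_ft", c(energy = 100)),
    bioavailability = sys$bioavailability[0, ],
    waste = tibble::tibble(region_id = "r1", food_group = "cereals",
                           fraction = 0.05, region_weight = 1),
    demographics = sys$demographics, nrv = sys$nrv
  ))
  b <- fit_baseline(fs$commodities, 2018, 10)
  # home waste mass = 400 * 0.05 = 20; (50 + 20) / 1000 = 7%
  expect_equal(waste_share(b, fs$food_types, fs$waste, "c_w"), 7,
               tolerance = 1e-12)
  # zero losses and zero fractions give 0%
  fs0 <- fs
  fs0$commodities$losses_kt <- 0
  fs0$waste$fraction <- 0
  b0 <- fit_baseline(fs0$commodities, 2018, 10)
  expect_equal(waste_share(b0, fs0$food_types, fs0$waste, "c_w"), 0)
})

test_that("per-capita mass converts kilotonnes per year to g per person per day", {
  sys <- tiny_system()
  av <- compute_availability(sys, 2018, 10)
  # 365 kt over 1e9 people is 1 g/person/day
  masses <- tibble::tibble(food_type_id = "ft", commodity_id = "c",
                           primary_food_group = "cereals",
                           edible_kt = 365, home_waste_kt = 0)
  expect_equal(per_capita_mass(masses, NULL, 1e9), 1, tolerance = 1e-12)
  expect_equal(per_capita_mass(av$masses, character(0), 1500), 0)
  # additivity over a partition by commodity
  total <- per_capita_mass(av$masses, NULL, av$population)
  parts <- per_capita_mass(av$masses, "c_a", av$population) +
    per_capita_mass(av$masses, "milk", av$population)
  expect_equal(total, parts, tolerance = 1e-12)
})

test_that("DIAAS is the limiting digestibility-adjusted ratio to the reference", {
  ref <- c(lysine = 48, leucine = 61, methionine = 23, threonine = 25)
  # profile equal to the reference at full digestibility scores exactly 1
  d <- diaas(ref, stats::setNames(rep(1, 4), names(ref)), ref)
  expect_equal(d$score, 1)
  # doubling the profile at half digestibility cancels
  d2 <- diaas(ref * 2, stats::setNames(rep(0.5, 4), names(ref)), ref)
  expect_equal(d2$score, 1)
  # sulfur amino acid at 0.8 of the reference with digestibility 0.92
  prof <- ref; prof["methionine"] <- 0.8 * ref[["methionine"]]
  dig <- stats::setNames(rep(1, 4), names(ref)); dig["methionine"] <- 0.92
  d3 <- diaas(prof, dig, ref)
  expect_equal(d3$score, 0.92 * 0.8, tolerance = 1e-12)
  expect_equal(d3$limiting, "methionine")
  # scale invariance and monotonicity in digestibility
  d4 <- diaas(prof * 3.5, dig, ref * 3.5)
  expect_equal(d4$score, d3$score, tolerance = 1e-12)
  dig_up <- dig; dig_up["methionine"] <- 0.95
  expect_gte(diaas(prof, dig_up, ref)$score, d3$score)
  expect_error(diaas(prof, dig, ref * 0), "positive",
               class = "nutriflow_schema_error")
})

test_that("percent contributions sum to 100 and removal subtracts exactly", {
  bundle <- generate_system(generator_config(n_commodities = 5, seed = 9,
                                             food_types_per_commodity = c(1, 3)))
  av <- compute_availability(bundle$system)
  ids <- unique(bundle$system$commodities$commodity_id)
  for (n in c("energy", "calcium", "lysine")) {
    pcts <- vapply(ids, function(id) contribution_percent(av, id, n),
                   numeric(1))
    expect_equal(sum(pcts), 100, tolerance = 1e-6)
  }
  # removing a commodity lowers totals by exactly its contribution
  tot <- nutriflow:::nutrient_totals(av)
  drop_id <- ids[2]
  sys2 <- bundle$system
  keep <- sys2$commodities$commodity_id != drop_id
  sys2$commodities <- sys2$commodities[keep, ]
  sys2$food_types <- sys2$food_types[sys2$food_types$commodity_id != drop_id, ]
  av2 <- compute_availability(food_system(sys2))
  tot2 <- nutriflow:::nutrient_totals(av2)
  expect_equal(tot2, tot - nutriflow:::nutrient_totals(av, drop_id),
               tolerance = 1e-9)
})
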