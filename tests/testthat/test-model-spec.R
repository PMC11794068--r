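test_that("validation flags duplicates, unresolved references, cycles, bad delays and inflows", {
  expect_length(sd_validate(japan_pricing_model()), 0)
  expect_length(sd_validate(toy_chain_model()), 0)

  cyc <- sd_model(sd_aux("A", sd_ref("B")), sd_aux("B", sd_ref("A")),
                  sd_stock("s", inflow = "A"))
  issues <- sd_validate(cyc)
  expect_length(issues, 1)
  expect_match(issues, "cycle")
  expect_match(issues, "A")
  expect_match(issues, "B")

  unresolved <- sd_model(sd_aux("a", sd_ref("X")), sd_stock("s", inflow = "a"))
  issues <- sd_validate(unresolved)
  expect_length(issues, 1)
  expect_match(issues, "unresolved")
  expect_match(issues, "'X'")

  dup <- sd_model(sd_constant("k", 1), sd_constant("k", 2),
                  sd_stock("s", inflow = "k"))
  expect_match(sd_validate(dup), "duplicate", all = FALSE)

  # delay edges may close loops without raising a cycle issue
  delay_loop <- sd_model(
    sd_constant("k", 1),
    sd_aux("a", sd_ref("k"), sd_delay1("b", 2)),
    sd_aux("b", sd_ref("a")),
    sd_stock("s", inflow = "b"))
  expect_length(sd_validate(delay_loop), 0)

  bad_delay <- sd_model(sd_constant("k", 1),
                        sd_aux("a", sd_delay1("k", 2)),
                        sd_stock("s", inflow = "a"))
  bad_delay$variables[["a"]]$terms[[1]]$delay$delay_time <- -1
  expect_match(sd_validate(bad_delay), "non-positive delay", all = FALSE)

  bad_stock <- sd_model(sd_constant("k", 1), sd_stock("s", inflow = "nope"))
  expect_match(sd_validate(bad_stock), "unresolved inflow", all = FALSE)
})

test_that("dependency order is topological with declaration-order tie-breaking", {
  expect_equal(sd_dependency_order(toy_chain_model()), c("c", "b", "a"))

  jp <- sd_dependency_order(japan_pricing_model())
  expect_lt(match("new mechanism", jp), match("new action part", jp))
  expect_lt(match("sakigake premium", jp),
            match("new drug pricing decision variation", jp))
  expect_setequal(jp, names(Filter(function(v) v$kind == "auxiliary",
                                   japan_pricing_model()$variables)))

  no_aux <- sd_model(sd_constant("k", 1), sd_stock("s", inflow = "k"))
  expect_equal(sd_dependency_order(no_aux), character(0))

  cyc <- sd_model(sd_aux("A", sd_ref("B")), sd_aux("B", sd_ref("A")),
                  sd_stock("s", inflow = "A"))
  expect_error(sd_dependency_order(cyc), "cycle")

  # declaration order breaks ties among independent auxiliaries
  ind <- sd_model(sd_aux("z", sd_lit(1)), sd_aux("m", sd_lit(1)),
                  sd_aux("a", sd_lit(1)), sd_stock("s", inflow = "a"))
  expect_equal(sd_dependency_order(ind), c("z", "m", "a"))
})

test_that("census counts variables by kind", {
  expect_equal(sd_census(japan_pricing_model()),
               c(constant = 17L, auxiliary = 33L, stock = 1L))
  expect_equal(sd_census(sd_model(name = "empty")),
               c(constant = 0L, auxiliary = 0L, stock = 0L))
  expect_equal(sd_census(sd_model(sd_constant("a", 1), sd_constant("b", 2))),
               c(constant = 2L, auxiliary = 0L, stock = 0L))
})

test_that("constant accessors read and replace values", {
  m <- toy_chain_model()
  expect_equal(sd_constants(m), c(k = 4))
  m2 <- sd_set_constant(m, "k", 10)
  expect_equal(sd_constants(m2), c(k = 10))
  expect_error(sd_set_constant(m, "nope", 1), "unknown")
  expect_error(sd_set_constant(m, "a", 1), "not a constant")
})

test_that("input scaling multiplies constants, literals and stock initials", {
  m <- sd_model(sd_constant("k", 3),
                sd_aux("a", sd_lit(2), sd_ref("k")),
                sd_stock("s", inflow = "a", initial = 7))
  m2 <- sd_scale_inputs(m, 3)
  expect_equal(m2$variables[["k"]]$value, 9)
  expect_equal(m2$variables[["a"]]$terms[[1]]$literal, 6)
  expect_equal(m2$variables[["s"]]$initial, 21)
})
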