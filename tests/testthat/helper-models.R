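# Small hand-built models shared across tests.

toy_chain_model <- function() {
  # a refs b refs c; one stock integrating a
  sd_model(
    sd_constant("k", 4),
    sd_aux("c", sd_ref("k", 0.5)),
    sd_aux("b", sd_lit(1), sd_ref("c")),
    sd_aux("a", sd_ref("b", 2)),
    sd_stock("s", inflow = "a"),
    name = "chain"
  )
}

single_delay_model <- function(input = 8, delay_time = 5,
                               init_policy = "zero") {
  sd_model(
    sd_constant("input", input),
    sd_aux("out", sd_delay1("input", delay_time, init_policy = init_policy)),
    sd_stock("cum", inflow = "out"),
    name = "single-delay"
  )
}
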