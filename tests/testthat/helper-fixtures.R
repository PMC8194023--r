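# Shared helpers: independent oracles and tiny hand-built models.

# Independent oracle for the squashing function: the direct closed form,
# evaluated naively (safe for moderate |beta * x|).
squashing_oracle <- function(x, beta) {
  (1 / beta) * log((1 + exp(beta * x)) / (1 + exp(beta * (x - 1))))
}

# A one-layer "network" whose two sigmoid outputs are constants
# plogis(b1), plogis(b2): lets recommender/metric tests pin model outputs.
constant_model <- function(p_time, p_tk, input_dim = 10L) {
  structure(
    list(kind = "dense",
         layers = list(dense_layer(matrix(0, 2L, input_dim),
                                   stats::qlogis(c(p_time, p_tk)),
                                   "sigmoid", name = "head")),
         spec = list(input_dim = input_dim, output_dim = 2L),
         input_names = paste0("V", seq_len(input_dim))),
    class = "lonn_model"
  )
}

# Recommender pair wired from two constant models, with a normalization
# spec fitted on a small fixture cohort.
constant_pair <- function(p_full, p_pos, cohort = NULL) {
  if (is.null(cohort)) cohort <- generate_fixture_cohort(50, seed = 99L)
  structure(
    list(model_full = constant_model(p_full[1L], p_full[2L]),
         model_positive = constant_model(p_pos[1L], p_pos[2L]),
         norm_spec = fit_normalization(cohort),
         lonn_spec = NULL, config = NULL, min_time_days = 60),
    class = "recommender_pair"
  )
}

# All crisp 0/1 input combinations for a given fan-in.
crisp_inputs <- function(fan_in) {
  as.matrix(expand.grid(rep(list(c(0, 1)), fan_in)))
}

bool_gate <- function(kind, x) {
  switch(kind,
    AND = as.numeric(all(x == 1)),
    OR  = as.numeric(any(x == 1)),
    NOT = as.numeric(x[1L] == 0),
    NOR = as.numeric(all(x == 0))
  )
}
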