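# A stochastic test chooser: at episode start it commits to the "own" color
# with probability p_own, then steers like approach_color. Used to generate
# synthetic probe choices with a known bias for parameter-recovery tests.

make_biased_chooser <- function(p_own, own_color, other_color) {
  structure(list(kind = "biased_chooser", p_own = p_own,
                 own_color = own_color, other_color = other_color,
                 jitter = 0.05),
            class = c("test_chooser", "gs_scripted_policy"))
}

policy_act.test_chooser <- function(policy, state, agent_id, core_state = NULL,
                                    greedy = FALSE) {
  if (is.null(core_state)) {
    core_state <- if (runif(1) < policy$p_own) policy$own_color else policy$other_color
  }
  inner <- scripted_policy("approach_color", color = core_state,
                           jitter = policy$jitter)
  out <- policy_act(inner, state, agent_id)
  out$core_state <- core_state
  out
}

# register for S3 dispatch from inside the package namespace
registerS3method("policy_act", "test_chooser", policy_act.test_chooser,
                 envir = asNamespace("groupsim"))
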