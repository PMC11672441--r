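#' Engine registry
#'
#' All inference engines expose the same contract
#' `infer(kb, query, config) -> ranked_diagnosis`, so the benchmark treats
#' them as interchangeable plugins. `get_engine` builds one by name; for
#' FHAL the association matrices are trained once here against `kb` and
#' reused across queries.
#'
#' @param name One of `"mnfl"`, `"fhal"`, `"pfcmr"`.
#' @param kb The `knowledge_base` the engine will be queried against.
#' @param config A [fuzzy_config()] used by default at inference time.
#' @param pfcm A [pfcm_params()] (PFCM-R engine only).
#' @param tau,alpha FHAL hyper-parameters (see [fhal_train()]).
#' @return A list with elements `name` and `infer(kb, query, config)`.
#' @export
get_engine <- function(name = c("mnfl", "fhal", "pfcmr"), kb,
                       config = fuzzy_config(), pfcm = pfcm_params(),
                       tau = 0.5, alpha = 0.5) {
  name <- match.arg(name)
  infer <- switch(name,
    mnfl = function(kb, query, config = fuzzy_config())
      mnfl_infer(kb, query, config),
    fhal = local({
      w <- fhal_train(kb, tau = tau, alpha = alpha)
      function(kb, query, config = fuzzy_config())
        fhal_infer(kb, w, query, config)
    }),
    pfcmr = function(kb, query, config = fuzzy_config())
      pfcmr_infer(kb, query, pfcm, config))
  list(name = name, infer = infer)
}

#' @rdname get_engine
#' @export
list_engines <- function() c("mnfl", "fhal", "pfcmr")
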