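# Rendering of design tables and YAML-configured runs.

#' Design records in the standard table schema
#'
#' Formats one row per design with columns `K`, `pi_A`, `pi_R`, `n`, `a`,
#' `r`, `alpha_prime`, `power`, `ess_null`, `ess_alt`, `max_n`. Error
#' rates and power are rendered to 3 decimal places, expected sample sizes
#' to 1, and real-valued (normal-engine) boundaries to 2; unevaluated
#' fields render as `"NA"`. Internal values are never rounded; rounding is
#' display-only.
#'
#' @param designs A list of [gs_design()] objects, or a tibble from
#'   [grid_search()].
#' @param problem A [design_problem()] used to evaluate operating
#'   characteristics where they are not already present.
#' @param plans Optional list of [spending_plan()]s aligned with `designs`.
#' @return A tibble of character-formatted columns, one row per design.
#' @export
design_table <- function(designs, problem = NULL, plans = NULL) {
  if (tibble::is_tibble(designs)) {
    plans <- purrr::map2(designs$pi_A, designs$pi_R,
                         function(a, r) spending_plan(a, r))
    designs <- designs$design
  }
  if (inherits(designs, "gs_design")) designs <- list(designs)
  if (length(designs) == 0) stop("no designs to render", call. = FALSE)
  rows <- purrr::imap(designs, function(d, i) {
    p <- if (!is.null(plans) && length(plans) >= i) plans[[i]] else NULL
    oc <- if (!is.null(problem)) operating_characteristics(d, problem)
    fmt_b <- function(v) {
      if (d$engine == "exact") {
        paste(format(v, trim = TRUE), collapse = ", ")
      } else {
        paste(sprintf("%.2f", v), collapse = ", ")
      }
    }
    wrap <- function(s) if (d$K > 1) paste0("(", s, ")") else s
    tibble::tibble(
      K = d$K,
      pi_A = if (is.null(p)) "NA" else
        wrap_vec(p$pi_A, function(v) format(v, trim = TRUE), d$K > 1),
      pi_R = if (is.null(p)) "NA" else
        wrap_vec(p$pi_R, function(v) format(v, trim = TRUE), d$K > 1),
      n = d$n,
      a = wrap(fmt_b(d$a)),
      r = wrap(fmt_b(d$r)),
      alpha_prime = if (is.null(oc)) "NA" else sprintf("%.3f", oc$alpha_max),
      power = if (is.null(oc)) "NA" else sprintf("%.3f", 1 - oc$beta_max),
      ess_null = if (is.null(oc)) "NA" else sprintf("%.1f", oc$ess_null),
      ess_alt = if (is.null(oc)) "NA" else sprintf("%.1f", oc$ess_alt),
      max_n = 2L * d$K * d$n
    )
  })
  dplyr::bind_rows(rows)
}

wrap_vec <- function(v, f, wrap) {
  s <- paste(f(v), collapse = ", ")
  if (wrap) paste0("(", s, ")") else s
}

#' Run a YAML-configured design task
#'
#' Reads a configuration (file path or list) describing the design problem
#' and one of four modes — `single_plan` (derive and size one spending
#' plan), `grid` (near-optimal spending search), `exhaustive` (optimal
#' two-stage exact search), `validate` (simulate a given design) — runs it,
#' and optionally writes CSV and/or JSON outputs in the standard schema.
#'
#' @param config Path to a YAML file or an equivalent named list. Required
#'   fields: `problem` (with `lambda0`, `lambda1`, `delta`, `alpha`,
#'   `beta`, `lambda_ess`), `mode`, and `engine`/`K` plus the
#'   mode-specific fields (`pi_A`/`pi_R`, `weights`, `design`,
#'   `lambda1`/`lambda2`/`replicates`/`seed`).
#' @param csv,json Optional output paths.
#' @param verbose Log evaluated candidates.
#' @return A list with the constructed `problem`, the mode's result
#'   (`design`, `table`, or validation tibble), invisibly.
#' @export
run_design_config <- function(config, csv = NULL, json = NULL,
                              verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  req <- function(field, where = config) {
    if (is.null(where[[field]])) {
      stop("config field `", field, "` is missing", call. = FALSE)
    }
    where[[field]]
  }
  pr <- req("problem")
  problem <- design_problem(
    lambda0 = as.numeric(req("lambda0", pr)),
    lambda1 = as.numeric(req("lambda1", pr)),
    delta = req("delta", pr), alpha = req("alpha", pr),
    beta = req("beta", pr),
    lambda_ess = pr$lambda_ess %||% min(as.numeric(pr$lambda1))
  )
  mode <- match.arg(req("mode"),
                    c("single_plan", "grid", "exhaustive", "validate"))
  engine <- config$engine %||% "exact"
  result <- switch(
    mode,
    single_plan = {
      plan <- spending_plan(as.numeric(req("pi_A")), as.numeric(req("pi_R")))
      d <- find_group_size(plan, problem, engine,
                           n_cap = config$n_cap %||% 500L)
      if (inherits(d, "gs_notfound")) {
        stop("no feasible group size for the requested plan", call. = FALSE)
      }
      list(design = d,
           table = design_table(list(d), problem, plans = list(plan)))
    },
    grid = {
      w <- as.numeric(req("weights"))
      check_weights(w)
      plans <- spending_grid(problem, K = req("K"))
      res <- grid_search(plans, w, problem, engine,
                         n_cap = config$n_cap, verbose = verbose)
      if (nrow(res) == 0) stop("every plan in the grid was infeasible",
                               call. = FALSE)
      list(search = res, design = res$design[[1]],
           table = design_table(res, problem))
    },
    exhaustive = {
      w <- as.numeric(req("weights"))
      check_weights(w)
      d <- exhaustive_search_k2(problem, w, epsilon = config$epsilon %||% 1e-7,
                                verbose = verbose)
      if (inherits(d, "gs_notfound")) {
        stop("no feasible design in the search box", call. = FALSE)
      }
      list(design = d, table = design_table(list(d), problem))
    },
    validate = {
      ds <- req("design")
      d <- gs_design(K = req("K", ds), n = req("n", ds),
                     a = as.numeric(req("a", ds)),
                     r = as.numeric(req("r", ds)),
                     engine = ds$engine %||% engine)
      list(validation = validate_design(
        d, lambda1 = req("lambda1"), lambda2 = req("lambda2"),
        replicates = config$replicates %||% 10000L,
        seed = config$seed %||% 1L))
    }
  )
  if (!is.null(csv) && !is.null(result$table)) {
    utils::write.csv(result$table, csv, row.names = FALSE)
  }
  if (!is.null(json)) {
    out <- result[setdiff(names(result), "design")]
    if (!is.null(result$design)) {
      d <- result$design
      out$design <- list(K = d$K, n = d$n, a = d$a, r = d$r,
                         engine = d$engine)
    }
    jsonlite::write_json(out, json, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  }
  invisible(c(list(problem = problem), result))
}
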