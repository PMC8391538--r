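#!/usr/bin/env Rscript
# Thin command-line front end over the abcdp package.
#
#   Rscript scripts/abcdp.R simulate  --model mixture|polynomial --seed S --out DIR
#   Rscript scripts/abcdp.R run       --config cfg.yaml [--seed S] --out DIR
#   Rscript scripts/abcdp.R sweep     --config cfg.yaml --eps-total 0.5,1,10,inf --out DIR
#   Rscript scripts/abcdp.R flip-prob --b 0.1 --eps-abc 0.2 --rho-grid 0,0.1,...  --out FILE.csv
#
# `run` writes the privacy-safe results bundle (results.json, accepted
# parameter CSVs, config.yaml) into --out.

suppressPackageStartupMessages({
  library(abcdp)
  library(optparse)
})

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1) stop("usage: abcdp.R <simulate|run|sweep|flip-prob> ...")
verb <- argv[1]
rest <- argv[-1]

parse_nums <- function(s) {
  vapply(strsplit(s, ",")[[1]], function(x) {
    if (tolower(x) %in% c("inf", "infinity")) Inf else as.numeric(x)
  }, numeric(1), USE.NAMES = FALSE)
}

opts_for <- function(...) {
  parse_args(OptionParser(option_list = list(...)), args = rest)
}

if (verb == "simulate") {
  o <- opts_for(
    make_option("--model", default = "mixture"),
    make_option("--seed", type = "integer", default = 1L),
    make_option("--n", type = "integer", default = 1000L),
    make_option("--out", default = "simulated.csv"))
  set.seed(o$seed)
  data <- switch(o$model,
    mixture = data.frame(y = sample_mixture_data(mixture_theta_star(),
                                                 o$n)[, 1]),
    polynomial = synthetic_outbreak_counts(),
    stop("unknown model: ", o$model))
  write.csv(data, o$out, row.names = FALSE)
  cat("wrote", o$out, "(", nrow(data), "records )\n")

} else if (verb == "run") {
  o <- opts_for(
    make_option("--config", default = NULL),
    make_option("--seed", type = "integer", default = NULL),
    make_option("--out", default = "results"))
  cfg <- if (is.null(o$config)) run_config() else read_run_config(o$config)
  if (!is.null(o$seed)) cfg <- do.call(run_config,
                                       utils::modifyList(unclass(cfg),
                                                         list(seed = o$seed)))
  res <- run_experiment(cfg, out_dir = o$out)
  print(res)

} else if (verb == "sweep") {
  o <- opts_for(
    make_option("--config", default = NULL),
    make_option("--eps-total", dest = "eps_total", default = "0.5,1,10,inf"),
    make_option("--out", default = "sweep"))
  base_cfg <- if (is.null(o$config)) run_config() else
    read_run_config(o$config)
  for (eps in parse_nums(o$eps_total)) {
    cfg <- do.call(run_config, utils::modifyList(unclass(base_cfg),
                                                 list(epsilon_total = eps)))
    tag <- if (is.infinite(eps)) "inf" else format(eps)
    res <- run_experiment(cfg,
                          out_dir = file.path(o$out, paste0("eps_", tag)))
    print(res)
  }

} else if (verb == "flip-prob") {
  o <- opts_for(
    make_option("--N", default = "10,100,1000"),
    make_option("--c", dest = "cc", default = "10,100,1000"),
    make_option("--eps-total", dest = "eps_total", default = "0.5,1,10,100"),
    make_option("--eps-abc", dest = "eps_abc", type = "double",
                default = 0.2),
    make_option("--rho-grid", dest = "rho_grid", default = NULL),
    make_option("--n-rho", dest = "n_rho", type = "integer", default = 100L),
    make_option("--seed", type = "integer", default = 1L),
    make_option("--out", default = "flip_prob.csv"))
  rho <- if (!is.null(o$rho_grid)) parse_nums(o$rho_grid) else {
    set.seed(o$seed)
    runif(o$n_rho)
  }
  tab <- flip_prob_table(N_grid = parse_nums(o$N),
                         c_grid = parse_nums(o$cc),
                         eps_total_grid = parse_nums(o$eps_total),
                         rho = rho, epsilon_abc = o$eps_abc)
  write.csv(tab, o$out, row.names = FALSE)
  cat("wrote", o$out, "(", nrow(tab), "rows )\n")

} else {
  stop("unknown verb: ", verb,
       " (expected simulate, run, sweep or flip-prob)")
}
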