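# End-to-end orchestration: configuration, staged execution with logged
# seeds, and graph file formats (DOT, GraphML, CSV).

#' Export a network structure to a file
#'
#' DOT output renders undirected edges without arrowheads and labels edges
#' with bootstrap strengths when supplied; GraphML and CSV round-trip the
#' node and edge sets losslessly.
#'
#' @param network A `bn_graph`.
#' @param path Output file.
#' @param format `"dot"`, `"graphml"` or `"csv"`.
#' @param strengths Optional `arc_strengths` table for DOT edge labels.
#' @return `path`, invisibly.
#' @export
export_graph <- function(network, path, format = c("dot", "graphml", "csv"),
                         strengths = NULL) {
  format <- match.arg(format)
  a <- arcs(network); u <- undirected_edges(network)
  if (format == "dot") {
    lab <- function(x, y) {
      if (is.null(strengths)) return("")
      r <- strengths[strengths$from == x & strengths$to == y, ]
      if (!nrow(r)) return("")
      sprintf(" [label=\"%.2f\"]", r$adjacency_frequency[1])
    }
    lines <- c("digraph exacnet {",
               sprintf("  \"%s\";", network$nodes),
               if (nrow(a)) vapply(seq_len(nrow(a)), function(k)
                 sprintf("  \"%s\" -> \"%s\"%s;", a[k, 1], a[k, 2], lab(a[k, 1], a[k, 2])), ""),
               if (nrow(u)) vapply(seq_len(nrow(u)), function(k)
                 sprintf("  \"%s\" -> \"%s\" [dir=none%s];", u[k, 1], u[k, 2],
                         sub("^ \\[|\\]$", "", lab(u[k, 1], u[k, 2]))), ""),
               "}")
    writeLines(lines, path)
  } else if (format == "graphml") {
    doc <- xml2::xml_new_root("graphml",
                              xmlns = "http://graphml.graphdrawing.org/xmlns")
    gr <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "directed")
    for (nd in network$nodes) xml2::xml_add_child(gr, "node", id = nd)
    if (nrow(a)) for (k in seq_len(nrow(a))) {
      xml2::xml_add_child(gr, "edge", source = a[k, 1], target = a[k, 2],
                          directed = "true")
    }
    if (nrow(u)) for (k in seq_len(nrow(u))) {
      xml2::xml_add_child(gr, "edge", source = u[k, 1], target = u[k, 2],
                          directed = "false")
    }
    xml2::write_xml(doc, path)
  } else {
    df <- rbind(
      if (nrow(a)) data.frame(from = a[, 1], to = a[, 2], directed = TRUE),
      if (nrow(u)) data.frame(from = u[, 1], to = u[, 2], directed = FALSE))
    if (is.null(df)) df <- data.frame(from = character(0), to = character(0),
                                      directed = logical(0))
    attr(df, "nodes") <- network$nodes
    write.csv(cbind(df, node_set = paste(network$nodes, collapse = ";")),
              path, row.names = FALSE)
  }
  invisible(path)
}

#' Import a network structure from a file
#'
#' @param path Input file written by [export_graph()].
#' @param format `"dot"`, `"graphml"` or `"csv"`.
#' @return A `bn_graph`.
#' @export
import_graph <- function(path, format = c("dot", "graphml", "csv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    doc <- xml2::read_xml(path)
    ns <- xml2::xml_ns(doc)
    nodes <- xml2::xml_attr(xml2::xml_find_all(doc, ".//d1:node", ns), "id")
    ed <- xml2::xml_find_all(doc, ".//d1:edge", ns)
    src <- xml2::xml_attr(ed, "source"); tgt <- xml2::xml_attr(ed, "target")
    dir <- xml2::xml_attr(ed, "directed")
    und <- !is.na(dir) & dir == "false"
    bn_graph(nodes,
             arcs = if (any(!und)) cbind(src[!und], tgt[!und]),
             undirected = if (any(und)) cbind(src[und], tgt[und]))
  } else if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    nodes <- strsplit(df$node_set[1] %||% "", ";")[[1]]
    if (!length(nodes)) nodes <- unique(c(df$from, df$to))
    bn_graph(nodes,
             arcs = if (any(df$directed)) cbind(df$from[df$directed], df$to[df$directed]),
             undirected = if (any(!df$directed)) cbind(df$from[!df$directed], df$to[!df$directed]))
  } else {
    lines <- readLines(path)
    nd <- regmatches(lines, regexec("^\\s*\"([^\"]+)\";\\s*$", lines))
    nodes <- vapply(nd[vapply(nd, length, 1L) == 2L], `[[`, "", 2L)
    ed <- regmatches(lines, regexec("\"([^\"]+)\"\\s*->\\s*\"([^\"]+)\"(.*)", lines))
    ed <- ed[vapply(ed, length, 1L) == 4L]
    if (length(ed)) {
      src <- vapply(ed, `[[`, "", 2L); tgt <- vapply(ed, `[[`, "", 3L)
      und <- grepl("dir=none", vapply(ed, `[[`, "", 4L))
    } else { src <- tgt <- character(0); und <- logical(0) }
    bn_graph(unique(c(nodes, src, tgt)),
             arcs = if (any(!und)) cbind(src[!und], tgt[!und]),
             undirected = if (any(und)) cbind(src[und], tgt[und]))
  }
}

# ---- end-to-end pipeline ---------------------------------------------------

validate_run_config <- function(config) {
  defaults <- list(
    preset = "core9", n = 20000L, seed = 1L,
    input_csv = NULL, simulate_missingness = FALSE,
    algorithms = c("hc", "tabu", "pc_stable", "rsmax2_gs", "rsmax2_mmpc"),
    B = 1000L, threshold = 0.75, m_fraction = 1,
    whitelist = NULL, blacklist = NULL,
    discretization = "clinical", rebalance = FALSE,
    validation = list(scheme = "kfold", k = 10L),
    counterfactual_node = "crs", smoothing_alpha = 1,
    output_dir = "exacnet-run")
  config <- modifyList(defaults, config)
  if (!is.numeric(config$threshold) || config$threshold <= 0 || config$threshold > 1) {
    stop2("threshold must be in (0, 1]", class = "exacnet_config_error")
  }
  if (!is.numeric(config$B) || config$B < 1) {
    stop2("B must be >= 1", class = "exacnet_config_error")
  }
  if (!is.null(config$input_csv) && !file.exists(config$input_csv)) {
    stop2("input_csv '%s' does not exist", config$input_csv,
          class = "exacnet_config_error")
  }
  config
}

stage_guard <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop2("pipeline stage '%s' failed [E_%s]: %s", stage, toupper(stage),
          conditionMessage(e), class = "exacnet_stage_error")
  })
}

#' Run the full analysis pipeline
#'
#' Executes the staged analysis — simulate (or load) a cohort, recode
#' zeros/outliers, impute, discretize, bootstrap-consensus structure
#' learning under expert constraints, CPT fitting, counterfactual CRS
#' comparison, and cross-validation — writing every artifact plus a
#' manifest with the config hash and all derived stage seeds.
#'
#' @param config Named list; see [validate_run_config] defaults: `preset`,
#'   `n`, `seed`, `input_csv`, `algorithms`, `B`, `threshold`,
#'   `whitelist`/`blacklist`, `discretization`, `rebalance`, `validation`,
#'   `output_dir`.
#' @param verbose Print one line per stage.
#' @return Invisibly, a list with the main in-memory objects (`cohort`,
#'   `strengths`, `network`, `net`, `counterfactual`, `validation`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = list(), verbose = TRUE) {
  config <- validate_run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  seeds <- list()
  seed_for <- function(stage) {
    seeds[[stage]] <<- derive_seed(config$seed, stage)
    seeds[[stage]]
  }
  spec <- make_ground_truth_network(config$preset)

  cohort <- stage_guard("simulate", {
    if (!is.null(config$input_csv)) read_cohort_csv(config$input_csv)
    else {
      co <- sample_cohort(spec, config$n, seed_for("simulate"))
      if (isTRUE(config$simulate_missingness)) {
        co <- inject_missingness(co, spec, seed_for("missingness"))
      }
      co
    }
  })
  log_stage(verbose, "simulate", "n = %d", nrow(cohort))

  cohort <- stage_guard("recode", recode_zeros_and_outliers(cohort))
  write.csv(attr(cohort, "recode_log"), out("recode_log.csv"), row.names = FALSE)
  log_stage(verbose, "recode", "%d column(s) affected", nrow(attr(cohort, "recode_log")))

  if (anyNA(cohort)) {
    imp <- stage_guard("impute",
                       impute_iterative_forest(cohort, seed = seed_for("impute")))
    cohort <- imp$data
    log_stage(verbose, "impute", "%d iteration(s)", imp$iterations)
  }

  disc <- stage_guard("discretize", {
    if (identical(config$discretization, "hartemink")) {
      discretize_hartemink(cohort, columns = intersect(
        names(default_clinical_cuts()), names(cohort)))
    } else discretize_clinical(cohort)
  })
  write_discretization_json(disc$map, out("discretization_map.json"))
  write_cohort_csv(disc$data, out("cohort_discretized.csv"))
  log_stage(verbose, "discretize", "%d column(s) mapped", length(disc$map$columns))

  learn_cols <- intersect(pathway_nodes(spec), names(disc$data))
  ddata <- disc$data[learn_cols]
  constraints <- expert_constraints(config$whitelist, config$blacklist)
  strengths <- stage_guard("learn", bootstrap_strengths(
    ddata, algorithms = config$algorithms, B = config$B,
    m_fraction = config$m_fraction, constraints = constraints,
    seed = seed_for("learn")))
  write_strengths_csv(strengths, out("arc_strengths.csv"))
  avg <- averaged_network(strengths, config$threshold)
  avg <- apply_expert_constraints(avg, constraints)
  export_graph(avg, out("averaged_network.dot"), "dot", strengths = strengths)
  export_graph(avg, out("averaged_network.graphml"), "graphml")
  log_stage(verbose, "learn", "%d arc(s) at threshold %.2f",
            nrow(arcs(avg)) + nrow(undirected_edges(avg)), config$threshold)

  net <- stage_guard("fit", fit_cpts(pdag_to_dag(avg, best_effort = TRUE), ddata,
                                     smoothing_alpha = config$smoothing_alpha))
  write_dbn_json(net, out("fitted_network.json"))
  log_stage(verbose, "fit", "CPTs on %d node(s)", length(net$graph$nodes))

  cf <- stage_guard("counterfactual", {
    nd <- config$counterfactual_node
    if (nd %in% net$graph$nodes) {
      counterfactual_compare(net, nd, net$levels[[nd]], "future_exac")
    } else NULL
  })
  if (!is.null(cf)) write.csv(cf, out("counterfactual_crs.csv"), row.names = FALSE)

  val <- stage_guard("validate", {
    vs <- config$validation
    plan <- make_folds(cohort, vs$scheme %||% "kfold", k = vs$k %||% 10L,
                       seed = seed_for("folds"))
    cfg <- pipeline_config(discretization = config$discretization,
                           rebalance = config$rebalance,
                           constraints = constraints)
    cross_validate(cohort, cfg, plan, seed = seed_for("cv"))
  })
  write_validation_json(val, out("validation_report.json"))
  log_stage(verbose, "validate", "pooled macro AUC %.3f", val$pooled$auc_macro)

  cfg_file <- out("config.json")
  jsonlite::write_json(config[order(names(config))], cfg_file, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  artifacts <- c("recode_log.csv", "discretization_map.json",
                 "cohort_discretized.csv", "arc_strengths.csv",
                 "averaged_network.dot", "averaged_network.graphml",
                 "fitted_network.json", "counterfactual_crs.csv",
                 "validation_report.json")
  artifacts <- artifacts[file.exists(file.path(config$output_dir, artifacts))]
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    stage_seeds = seeds,
    artifacts = as.list(setNames(unname(tools::md5sum(file.path(config$output_dir,
                                                                artifacts))),
                                 artifacts)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE, digits = NA)
  log_stage(verbose, "manifest", "config hash %s", manifest$config_hash)
  invisible(list(cohort = cohort, strengths = strengths, network = avg, net = net,
                 counterfactual = cf, validation = val, manifest = manifest))
}
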