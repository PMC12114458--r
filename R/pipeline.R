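# End-to-end orchestration: validate a sample plan, run the gating ->
# quantification -> MBC-calling pipeline over one assay, and keep a
# per-step event-count audit trail (raw >= post-threshold >= post-doublet
# >= gated for every sample).

#' Validate a sample plan
#'
#' A plan is a data frame with columns `sample_id` (or `file`), `strain`,
#' `disinfectant`, `concentration` (NA for controls) and `role`
#' (`treated`, `growth_control`, `negative_control`, `unstained`,
#' `single_stain`, `heat_killed`). Each (strain, disinfectant) assay must
#' contain exactly one growth control and one negative control, and its
#' treated concentrations must form a two-fold descending ladder.
#'
#' @param plan data frame as described.
#' @return the plan, invisibly; stops with a message listing every
#'   violation otherwise.
#' @export
validate_sample_plan <- function(plan) {
  stopifnot(is.data.frame(plan))
  needed <- c("strain", "disinfectant", "concentration", "role")
  missing_cols <- setdiff(needed, names(plan))
  if (length(missing_cols)) {
    stop("plan is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  roles <- c("treated", "growth_control", "negative_control", "unstained",
             "single_stain", "heat_killed")
  problems <- character(0)
  bad_role <- !plan$role %in% roles
  if (any(bad_role)) {
    problems <- c(problems, paste0("row ", which(bad_role),
                                   ": unknown role '", plan$role[bad_role], "'"))
  }
  for (key in split(seq_len(nrow(plan)),
                    paste(plan$strain, plan$disinfectant, sep = " / "))) {
    sub <- plan[key, ]
    tag <- paste(sub$strain[1], sub$disinfectant[1], sep = " / ")
    if (sum(sub$role == "growth_control") != 1) {
      problems <- c(problems, paste0(tag, ": needs exactly one growth_control"))
    }
    if (sum(sub$role == "negative_control") != 1) {
      problems <- c(problems, paste0(tag, ": needs exactly one negative_control"))
    }
    conc <- sort(sub$concentration[sub$role == "treated"], decreasing = TRUE)
    if (length(conc) >= 2) {
      ratio <- conc[-length(conc)] / conc[-1]
      if (any(abs(ratio - 2) > 1e-9)) {
        problems <- c(problems, paste0(tag, ": treated concentrations are not ",
                                       "a two-fold descending ladder"))
      }
    }
    if (any(sub$role == "treated" & is.na(sub$concentration))) {
      problems <- c(problems, paste0(tag, ": treated row without concentration"))
    }
  }
  if (length(problems)) {
    stop("invalid sample plan:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(plan)
}

# gate one sample through threshold -> doublet exclusion -> bacteria gate
gate_sample <- function(table, gate, cfg) {
  thr <- apply_event_threshold(table, cfg)
  dbl <- exclude_doublets(thr, cfg)
  gated <- apply_gate(dbl$table, gate)
  list(n_raw = n_events(table),
       n_threshold = n_events(thr),
       n_singlet = n_events(dbl$table),
       n_gated = gated$n_inside,
       table = gated$inside)
}

#' Run the full assay pipeline on one experiment
#'
#' Steps: build the bacteria gate from the (thresholded, singlet) growth
#' control by SYTO9 back-gating; gate every sample through threshold ->
#' doublet exclusion -> bacteria gate; convert gated counts to events/s;
#' normalize against the controls; classify each ladder concentration and
#' call the MBC.
#'
#' @param experiment list with `growth_control`, `negative_control` and
#'   `treated` (event tables named by concentration), e.g. from
#'   [simulate_experiment()].
#' @param gating a [gating_config()].
#' @param threshold normalized-count classification cut-off.
#' @param policy MBC-calling policy, see [call_mbc()].
#' @param unstained optional unstained control for the SYTO9 cut.
#' @return list with `counts` (per-sample data frame: sample_id, role,
#'   concentration, n_gated, duration_s, rate, normalized), `mbc`
#'   (an `mbc_call`), `gate`, `audit` (per-step event counts) and `config`.
#' @export
run_pipeline <- function(experiment, gating = gating_config(),
                         threshold = 0.1, policy = "strict",
                         unstained = NULL) {
  stopifnot(all(c("growth_control", "negative_control", "treated") %in%
                  names(experiment)))
  pc_raw <- experiment$growth_control
  pc_thr <- apply_event_threshold(pc_raw, gating)
  pc_sgl <- exclude_doublets(pc_thr, gating)$table
  gate <- build_bacteria_gate(pc_sgl, unstained = unstained, cfg = gating)

  conc <- as.numeric(names(experiment$treated))
  samples <- c(list(growth_control = pc_raw,
                    negative_control = experiment$negative_control),
               experiment$treated)
  roles <- c("growth_control", "negative_control",
             rep("treated", length(conc)))
  gated <- lapply(samples, gate_sample, gate = gate, cfg = gating)
  audit <- data.frame(
    sample_id = names(samples), role = roles,
    concentration = c(NA, NA, conc),
    n_raw = vapply(gated, `[[`, numeric(1), "n_raw"),
    n_threshold = vapply(gated, `[[`, numeric(1), "n_threshold"),
    n_singlet = vapply(gated, `[[`, numeric(1), "n_singlet"),
    n_gated = vapply(gated, `[[`, numeric(1), "n_gated"),
    row.names = NULL)
  dur <- vapply(samples, function(s) s$acquisition$duration_s, numeric(1))
  rate <- audit$n_gated / dur
  rate_pc <- rate[1]; rate_nc <- rate[2]
  normalized <- c(normalize_rate(rate_pc, rate_nc, rate_pc),
                  normalize_rate(rate_nc, rate_nc, rate_pc),
                  normalize_rate(rate[-(1:2)], rate_nc, rate_pc))
  counts <- data.frame(sample_id = audit$sample_id, role = roles,
                       concentration = audit$concentration,
                       n_gated = audit$n_gated, duration_s = unname(dur),
                       rate = unname(rate), normalized = unname(normalized),
                       row.names = NULL)
  ord <- order(conc, decreasing = TRUE)
  mbc <- call_mbc(conc[ord], normalized[-(1:2)][ord],
                  threshold = threshold, policy = policy)
  list(counts = counts, mbc = mbc, gate = gate, audit = audit,
       config = list(gating = gating, threshold = threshold, policy = policy,
                     version = as.character(utils::packageVersion("cytocide"))))
}

#' Run the pipeline from a file-based sample plan
#'
#' Reads every file referenced by the plan with [read_events()], groups
#' rows by (strain, disinfectant) and runs [run_pipeline()] per assay.
#'
#' @param plan validated sample plan with a `file` column.
#' @param ... passed to [run_pipeline()].
#' @return named list of per-assay pipeline reports.
#' @export
run_pipeline_files <- function(plan, ...) {
  validate_sample_plan(plan)
  if (!"file" %in% names(plan)) stop("plan needs a 'file' column", call. = FALSE)
  out <- list()
  for (idx in split(seq_len(nrow(plan)),
                    paste(plan$strain, plan$disinfectant, sep = " / "))) {
    sub <- plan[idx, ]
    tag <- paste(sub$strain[1], sub$disinfectant[1], sep = " / ")
    read_row <- function(r) read_events(sub$file[r])
    treated_rows <- which(sub$role == "treated")
    treated_rows <- treated_rows[order(sub$concentration[treated_rows],
                                       decreasing = TRUE)]
    treated <- lapply(treated_rows, read_row)
    names(treated) <- as.character(sub$concentration[treated_rows])
    unst_row <- which(sub$role == "unstained")
    out[[tag]] <- run_pipeline(
      list(growth_control = read_row(which(sub$role == "growth_control")),
           negative_control = read_row(which(sub$role == "negative_control")),
           treated = treated),
      unstained = if (length(unst_row)) read_row(unst_row[1]) else NULL,
      ...)
  }
  out
}
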