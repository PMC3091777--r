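# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small except where a check is about large-sample
# behaviour.

# one-group paired config used by most IBMT checks
small_config <- function(seed, n_probes = 2000L, n_subjects = 4L,
                         sex = "F", time = "4h", ...) {
  simulation_config(n_probes = n_probes,
                    groups = data.frame(sex = sex, time = time,
                                        n_subjects = n_subjects,
                                        stringsAsFactors = FALSE),
                    seed = seed, ...)
}

paired_cmp <- function(sex = "F", time = "4h") {
  comparison(paste0(sex, "_", time, "_paired"), "paired",
             case = list(sex = sex, time = time, arm = "exercised"),
             reference = list(sex = sex, time = time, arm = "control"))
}

# minimal hand-built study: values chosen by the caller
manual_study <- function(values, sex = "M", time = "24h") {
  n_subj <- ncol(values) / 2L
  subjects <- sprintf("s%d", seq_len(n_subj))
  design <- data.frame(
    sample_id = colnames(values),
    subject_id = rep(subjects, 2L),
    sex = sex, arm = rep(c("exercised", "control"), each = n_subj),
    time = time, stringsAsFactors = FALSE)
  expression_study(values, design)
}

# tiny gene-set collection over an explicit universe
sets_from_list <- function(...) gene_set_collection(list(...))
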