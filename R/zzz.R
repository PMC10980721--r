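# quiet R CMD check notes for data.table non-standard evaluation
utils::globalVariables(c(
  ".", ".I", ".N", ".SD", "V1", "V3", "a", "ac", "age", "age_cod", "b",
  "bcpnn_flag", "c", "caseid", "count", "d", "didx", "drug", "drug_seq",
  "drugname", "days", "ebgm05", "ebgm_flag", "event", "event_date",
  "event_dt", "fda_date", "fda_dt", "fda_key", "ic025", "in_cohort", "ev_key",
  "ev_key", "lab", "lambda", "level", "outc_cod", "outcome", "pct", "pid_key", "pri",
  "primaryid", "prod_ai", "prr_flag", "pt", "pt_key", "ptidx", "quarter",
  "realized_a", "ridx", "role_cod", "ror_flag", "ror_lo", "prr_lo", "sex",
  "signal", "soc_name", "soc_code", "start_date", "start_dt"))
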