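# betasort

Gating simulation and sort-timing analysis for stem-cell-derived islet
flow cytometry.

Stem-cell-derived islet (SC-islet) differentiations typically yield only
20–30% insulin-producing (INS+NKX6.1+) beta cells, alongside
alpha/polyhormonal, delta, enterochromaffin-like, ductal-like and
progenitor cells. CD133 (PROM1), an apical-polarity surface marker, is
brighter on newly formed beta cells than on alpha/polyhormonal cells —
but also on ductal-like cells; CD49a (ITGA1) is pan-endocrine and absent
from ductal epithelium. Sorting the CD49a-positive, CD133-high fraction
therefore enriches beta cells while excluding both alpha/polyhormonal
and ductal contaminants — provided the sort is timed for when the alpha
and beta CD133 distributions have separated.

`betasort` is the computational counterpart of that strategy, for
cytometrists and stem-cell biologists planning marker-based sorts:

* a **log-normal mixture simulator** of event-level cytometry data with
  ground-truth class labels and a stage-6 differentiation drift
  (`default_sc_islet_config()`, `simulate_events()`,
  `simulate_timecourse()`);
* the **relative position index (RPI)** quantifying alpha/beta overlap
  on a channel,

  RPI = clamp((P95_alpha − Q1_beta) / (Q3_beta − Q1_beta), 0, 1),

  where P95_alpha is the alpha/polyhormonal population's 0.95 percentile
  and [Q1_beta, Q3_beta] the beta interquartile range: 0 means distinct
  separation, 1 substantial overlap (`summarize_population()`,
  `relative_position_index()`, `rpi_from_table()`);
* **sort-window selection** over the time course (`rpi_timecourse()`,
  `select_sort_window()`);
* **deterministic gate simulation** — rank-exact top-fraction gates,
  fixed thresholds, largest-gap positive/negative splits, sequential
  (daughter-gate) composition — with purity, yield and per-class
  enrichment accounting (`apply_gates()`, `dual_sort_gates()`,
  `sort_outcome()`, `gating_report()`);
* **exact nonparametric replicate statistics** (`wilcoxon_signed_rank()`,
  `mann_whitney()`, `significance_stars()`);
* **I/O**: CSV event tables, a read-only subset of FCS 3.0/3.1, JSON/TSV
  reports and JSON gate/config serialization.

## Worked example

```r
library(betasort)
cfg <- default_sc_islet_config()

# When to sort: RPI across stage-6 days 0-7
tc <- rpi_timecourse(simulate_timecourse(cfg, n_per_day = 20000, days = 0:7))
round(tc$values, 4)
#> [1] 1.0000 0.7820 0.6672 0.4497 0.3313 0.2216 0.1139 0.0131
select_sort_window(tc)
#> <sort_window> stage-6 day 7 (criterion argmin, RPI 0.0131)

# What sorting achieves at day 7 (n = 10,000 events)
tab   <- simulate_events(cfg, 10000, timepoint = 7)
cd133 <- apply_gate(tab, gate_top_fraction("CD133", 0.20))
dual  <- apply_gates(tab, dual_sort_gates())

composition(tab)$fractions[["beta"]]     # 0.2471  unsorted beta purity
composition(cd133)$fractions[["beta"]]   # 0.6645  CD133-high only
composition(cd133)$fractions[["ductal"]] # 0.2670  ductal co-enriched!
composition(dual)$fractions[["beta"]]    # 0.9705  dual CD49a/CD133
```

The alpha and beta CD133 distributions overlap completely at day 0
(RPI 1.0) and separate progressively to near-zero overlap at day 7 — the
selected sorting window. There, a CD133-high (top 20%) gate alone lifts
beta purity from 25% to 66% but co-enriches polarized ductal-like cells
to 27% of events; pre-gating on CD49a-positive (endocrine) events before
taking the CD133-high tail removes them and reaches 97% beta purity in
this simulation.

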