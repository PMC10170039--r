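# netdea

Network slack-based efficiency analysis for hospitals (and other
service providers) with weakly disposable undesirable outputs.

## What it does

Health-system benchmarking has to reconcile three things that pull in
different directions: efficiency (treat many patients with few
resources), quality (few adverse events) and access (timely care).
`netdea` measures all three inside one frontier model.  Each
decision-making unit (DMU) is decomposed into divisions connected by
intermediate products — e.g. an operations division that turns beds,
staff hours and operating costs into patient volumes, which the clinical
divisions then turn into quality and access outcomes.  Each division is
scored by a non-radial slack-based measure (SBM), and undesirable
outputs (pressure ulcers, septicaemia, delayed appointments, waiting
days) are **weakly disposable**: a benchmark cannot discard adverse
events for free but only scale a peer's desirable and undesirable
outputs down jointly, through a per-peer abatement factor
$\theta_j = \varphi_j / (\mu_j + \varphi_j)$ obtained by splitting the
intensity vector $\lambda = \mu + \varphi$.

For division $k$ of DMU $o$ the package solves the linear program

$$\max \; \tfrac{1}{m_k}\textstyle\sum_i s_i^{k-}/x_{io}^k
  \quad(\text{input oriented; score } 1 - \text{opt})$$

subject to, for **every** division and link of the network,

$$x_o^k = X^k(\mu^k+\varphi^k) + s^{k-},\quad
  v_o^k = V^k\varphi^k - s^{k+},\quad
  u_o^k = U^k\varphi^k,$$
$$Z^{(k,h)}(\mu^h+\varphi^h) = Z^{(k,h)}(\mu^k+\varphi^k),\quad
  \textstyle\sum_j(\mu_j^k+\varphi_j^k) = 1 \;(\text{VRS}),$$

with $\mu, \varphi, s \ge 0$; output-oriented divisions maximise the
mean relative shortfall of desirable outputs and score
$1/(1+\text{opt})$.  The overall score is the mean of the divisional
scores.  On top of the fit the package provides:

* **CRS / VRS / scale efficiency** (`scale_efficiency()`),
* **Pearson screening** of near-collinear same-role variables, with
  clustering at a 0.95 threshold and sum-merging
  (`pearson_matrix()`, `find_clusters()`, `merge_variables()`),
* **sensitivity analysis** over single-representative substitutions
  within correlation clusters (`enumerate_variants()`,
  `compare_variants()`),
* **best-/worst-case scenario analysis** of each quality/access
  variable (`scenario_spec()`, `impact_analysis()`),
* a **synthetic hospital-panel generator** (`generate_panel()`) so the
  whole pipeline runs without any restricted data,
* four shipped network models `"A"`–`"D"` (`model_spec()`) and a YAML
  format for custom wirings, plus a thin CLI in `inst/scripts/netdea`.

## Worked example

```r
library(netdea)

panel <- generate_panel(synthetic_config(n_dmus = 8, n_periods = 2, seed = 1))
fit   <- netdea(panel, model = "B", rts = "vrs")
print(fit)
```

```
Network SBM efficiency fit (model 'B', VRS, 8 DMUs, 2 period(s))
Cross-period mean overall score: 0.9881 (min 0.9703); 3 DMU(s) on the frontier

Per-DMU cross-period averages:
 dmu group overall efficiency quality access
 H01     C  0.9884     1.0000       1 0.9653
 H02     D  0.9720     0.9997       1 0.9163
 H03     E  0.9906     1.0000       1 0.9718
 H04     C  0.9838     1.0000       1 0.9515
 H05     B  1.0000     1.0000       1 1.0000
 H06     B  1.0000     1.0000       1 1.0000
 H07     D  1.0000     1.0000       1 1.0000
 H08     F  0.9703     1.0000       1 0.9108
```

Each row is one hospital: `overall` is the mean of the three divisional
scores under model B (efficiency, quality, access); a DMU is on the
frontier only when every division is.  Here every hospital runs its
quality division efficiently, and the differences come from the access
division.  Scale efficiency compares the same fit under constant returns:

```r
crs <- netdea(panel, model = "B", rts = "crs")
head(scale_efficiency(fit, crs), 4)
```

```
  dmu       vrs       crs scale_efficiency
1 H01 0.9884256 0.9834626        0.9949789
2 H02 0.9719857 0.9614961        0.9892081
3 H03 0.9905868 0.9777476        0.9870387
4 H04 0.9838401 0.9838199        0.9999795
```

Values below 1 measure the share of inefficiency attributable to
operating away from the most productive scale.  Downstream analyses
follow the same pattern:

```r
clusters <- find_clusters(pearson_matrix(panel), model_spec("A"))
variants <- enumerate_variants(model_spec("A"), clusters)
impacts  <- impact_analysis(panel, model = "A", rts = "vrs")
```

See `vignette("network-sbm")` for the model, its assumptions, every
tunable parameter and the numerical design.

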