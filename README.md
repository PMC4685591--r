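# crownsim

Birth–death simulation of **crown-group emergence times**.

Every living clade is, by construction, a survivor: its *total group*
originated at the split from its closest living sister, and its *crown
group* — the clade of the most recent common ancestor (MRCA) of all its
living members — must have emerged somewhere between that origin and the
present. `crownsim` asks *where*, under the simplest neutral model: a
constant-rate birth–death process (speciation hazard *S*, extinction
hazard *E*, diversification rate *D = S − E*) run for a fixed duration *T*
and conditioned on survival to the present by rejection sampling.

The statistic is the **crown emergence fraction**

```
f = t(MRCA of extant tips) / T   ∈ [0, 1]
```

with `f = 0` exactly when both lineages of the initial split have living
descendants. Two classical sweeps are built in:

* **equal rates** — S = E ∈ {0.1, 0.3, 0.5, 0.7, 0.9}, T = 114, 50
  surviving trees per condition: the crown tends to emerge at ~50 % of the
  total group's age, whatever the absolute rates;
* **diversification** — E ∈ {0.1, …, 0.9} × D ∈ {0, 0.2, 0.4, 0.6},
  S = E + D, T = 15 (cells with S > 0.9 omitted and logged): the crown
  moves towards the total-group origin as D rises, and no condition mean
  exceeds 50 % by more than simulation noise.

## Worked example

One critical-rate condition (S = E = 0.5, T = 114), conditioned on
survival, 50 trees kept:

```r
library(crownsim)
res <- run_condition(0.5, 0.5, duration = 114,
                     policy = survival_policy(), seed = 2016)
res$summary
#>     S   E D   T  n mean_fraction sd_fraction lo_2sd hi_2sd acceptance_rate n_single
#> 1 0.5 0.5 0 114 50          0.54       0.325 -0.111   1.19          0.0421        2
```

Read: of the trees generated, 4.2 % survived with ≥ 2 extant lineages
(two more left a single survivor, for which the crown is undefined); over
the first 50 survivors the crown emerged on average at 54 % of the
total-group duration, with a ±2 s.d. band wide enough to cover the whole
interval — exactly the behaviour expected at criticality, centred near
50 %.

The crown machinery is easy to inspect on a five-tip fixture tree with
three living (`|A`) and two extinct (`|X`) tips:

```r
crown_fraction(make_fixture("five_tip_mixed"))
#>   tree_id n_extant crown_time fraction
#> 1      NA        3          2      0.2

write_newick(make_fixture("five_tip_mixed"), extant_only = TRUE)
#> [1] "((A|A:5,B|A:5):3,C|A:8):2;"
```

The MRCA of the three living tips sits at t = 2 of T = 10 (fraction 0.2);
pruning the extinct lineages leaves the crown clade, whose Newick root
edge `:2` is that same crown time. Full sweeps:

```r
eq <- run_equal_rates(sweep_spec("equal_rates", seed = 1))
dv <- run_diversification(sweep_spec("diversification", seed = 2))
write_sweep_csv(eq, "equal_rates.csv")
```

A thin command-line wrapper lives in `inst/scripts/sweep.R`
(`Rscript sweep.R --mode equal_rates --seed 1 --out results/`), and
`render_tree_figure(tree, "tree.png")` draws any tree with its crown clade
shaded grey and the origin starred.

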