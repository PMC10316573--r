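{
  "id": "coocnet-report/1",
  "description": "Consolidated pipeline report: parameters, per-group network summaries, community metrics.",
  "required": ["schema", "parameters", "n_samples", "n_taxa", "groups", "networks", "diversity_means"],
  "network_required": ["n_nodes", "n_edges", "edges_per_node_E_over_N", "mean_degree_2E_over_N", "acc", "apl", "diameter", "Q", "n_modules", "positive_edge_fraction"]
}
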