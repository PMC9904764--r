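2e4c842ae43e94003271191c44f59442  hps_params.tsv
eaac15055a5d8eaefbeb18a7ac47f462  phospho_params_synthetic.tsv
8bbba9216879c383e49d464a7477336a  khd_constants.tsv
ffd2d6a69d93d2730e691f018c636dbb  mj_matrix_synthetic.tsv
590cf1d7a58d4966cd5ee8928710a0cb  cdc15_phosphosites_synthetic.tsv
4a6fdf8eedd8bae86399615fc673e350  cdc15_idr_synthetic.fasta
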