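{"seed":42,"files":{"name":["architecture.tsv","repeat_hits.tsv","census.json","groups.tsv","tree_stage1.nwk","tree_stage2.nwk","motifs_meme.txt","motif_occurrences.tsv","motif_architectures.tsv","logo_motif1.svg","logo_motif2.svg","gene_structure.tsv","chromosome_distribution.tsv","chromosomes.svg","homology_edges.tsv","orthologs.tsv","paralogs.tsv","clusters.tsv","physchem.tsv","physchem_summary.json","expression.tsv","trends.tsv"],"md5":["47499fa0caa4b205f858316149ff3e76","1818686db436c20fdf21c880ed9c38af","dbbdb6e0157677a034e8b7cfb58e6b9b","a0fcc37b31782ed616741e35bbbd7a0f","8042c25c3f9a58f3139aa8fc6d60cdec","34f7641441e046b02ceb8e204083a586","ef6af6f56392493ea15588b765d7842f","25da644dff0d4ed00682fb2f19dd059f","d96368f3f8ba3eabca6931ca8f08cbde","69bf7c7659a545f7de474df08d15f584","0db6dda5284d816fa570f614f8ded89b","b88ff215e4c5a303b546977fe41c9cd9","285b87aba96d5942193020004daca614","7d2aa837f0d535ff7edc74f647d62d75","9c08712d4fa774d021d1cf830510aad6","ea9b956bf5dca355ad542033d8739091","c97ccd2def6c9838bf00ca3b91d83b26","2778e88e53cc5c8d5f66e42daebf90f8","e0de25436063d254d8c1c32180e1b6a5","cae4f60e03518d7864867e1e944795fd","c7b1b53f2318ca165d0ca72fa075c4ca","72638b3d0f71a587593f72a8c7daf3fb"],"bytes":[2165,2531,101,2687,2502,1953,24213,1861,635,129596,126966,2532,2272,4668,83594,743,17476,869,2413,163,5207,335]}}
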