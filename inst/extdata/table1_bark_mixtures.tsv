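sample	design_taxon	true_proportion	consensus_taxon	trnl_id	trnl_proportion	trnl_removed	rbcl_id	rbcl_proportion	rbcl_removed	median_id	median_proportion	median_removed
PC1	Fabaceae;Robinia;Robinia_pseudoacacia	0.4	Fabaceae;Robinia;Robinia_pseudoacacia	Fabaceae	0.813	0	Robinia pseudoacacia	0.958	0	Robinia pseudoacacia	0.886	0
PC1	Rosaceae;Prunus;Prunus_salicina	0.6	Rosaceae;Prunus	Prunus	0.187	0	Prunus	0.042	0	Prunus	0.114	0
PC2	Pinaceae;Pinus;Pinus_koreanus	0.78	Pinaceae;Pinus	Pinus	0.480	0	Pinus	0.620	0	Pinus	0.550	0
PC2	Salicaceae;Populus;Populus_tomentiglandulosa	0.22	Salicaceae;Populus	Populus	0.520	0	Populus	0.380	0	Populus	0.450	0
PC3	Salicaceae;Populus;Populus_tomentiglandulosa	0.55	Salicaceae;Populus	Populus	0.458	0	Populus	0.874	0	Populus	0.666	0
PC3	Fabaceae;Robinia;Robinia_pseudoacacia	0.16	Fabaceae;Robinia;Robinia_pseudoacacia	Fabaceae	0.393	0	Robinia pseudoacacia	0.100	0	Robinia pseudoacacia	0.247	0
PC3	Anacardiaceae;Rhus;Rhus_chinensis	0.27	Anacardiaceae;Rhus;Rhus_chinensis	Rhus chinensis	0.149	0	Anacardiaceae	0.026	0	Rhus chinensis	0.088	0
PC4	Rutaceae;Zanthoxylum;Zanthoxylum_schinifolium	0.34	Rutaceae;Zanthoxylum	Zanthoxylum	0.499	0	Zanthoxylum	0.453	0	Zanthoxylum	0.476	0
PC4	Lauraceae;Lindera;Lindera_obtusiloba	0.33	Lauraceae;Lindera;Lindera_obtusiloba	Lindera obtusiloba	0.366	0	Lindera obtusiloba	0.420	0	Lindera obtusiloba	0.393	0
PC4	Rosaceae;Prunus;Prunus_salicina	0.33	Rosaceae;Prunus	Prunus	0.135	0	Prunus	0.108	0	Prunus	0.121	0
PC5	Pinaceae;Pinus;Pinus_koreanus	0.27	Pinaceae;Pinus	Pinus	0.507	0	Pinus	0.504	0	Pinus	0.505	0
PC5	Simaroubaceae;Ailanthus;Ailanthus_altissima	0.22	Simaroubaceae;Ailanthus;Ailanthus_altissima	Ailanthus altissima	0.393	0	Ailanthus altissima	0.146	0	Ailanthus altissima	0.269	0
PC5	Paulowniaceae;Paulownia;Paulownia_tomentosa	0.4	Paulowniaceae;Paulownia	Paulownia	0.012	0	Paulownia	0.314	0	Paulownia	0.163	0
PC5	Lauraceae;Lindera;Lindera_obtusiloba	0.08	Lauraceae;Lindera;Lindera_obtusiloba	Lindera obtusiloba	0.031	0	Lindera obtusiloba	0.033	0	Lindera obtusiloba	0.032	0
PC5	Anacardiaceae;Rhus;Rhus_chinensis	0.03	Anacardiaceae;Rhus;Rhus_chinensis	Rhus chinensis	0.057	0	Anacardiaceae	0.004	1	Rhus chinensis	0.030	0
PC6	Salicaceae;Populus;Populus_tomentiglandulosa	0.24	Salicaceae;Populus	Populus	0.425	0	Populus	0.310	0	Populus	0.368	0
PC6	Paulowniaceae;Paulownia;Paulownia_tomentosa	0.02	Paulowniaceae;Paulownia	Paulownia	0.002	1	Paulownia	0.003	1	Paulownia	0.003	0
PC6	Anacardiaceae;Rhus;Rhus_chinensis	0.01	Anacardiaceae;Rhus;Rhus_chinensis	Rhus chinensis	0.001	1	Anacardiaceae	0.000	1	Rhus chinensis	0.001	1
PC6	Rutaceae;Zanthoxylum;Zanthoxylum_schinifolium	0.17	Rutaceae;Zanthoxylum	Zanthoxylum	0.079	0	Zanthoxylum	0.021	0	Zanthoxylum	0.050	0
PC6	Pinaceae;Pinus;Pinus_koreanus	0.46	Pinaceae;Pinus	Pinus	0.390	0	Pinus	0.647	0	Pinus	0.519	0
PC6	Simaroubaceae;Ailanthus;Ailanthus_altissima	0.07	Simaroubaceae;Ailanthus;Ailanthus_altissima	Ailanthus altissima	0.097	0	Ailanthus altissima	0.017	0	Ailanthus altissima	0.057	0
PC6	Lauraceae;Lindera;Lindera_obtusiloba	0.03	Lauraceae;Lindera;Lindera_obtusiloba	Lindera obtusiloba	0.005	1	Lindera obtusiloba	0.001	1	Lindera obtusiloba	0.003	0
PC7	Lauraceae;Lindera;Lindera_obtusiloba	0.005	Lauraceae;Lindera;Lindera_obtusiloba	Lindera obtusiloba	0.000	1	Lindera obtusiloba	0.000	1	Lindera obtusiloba	0.000	1
PC7	Pinaceae;Pinus;Pinus_koreanus	0.24	Pinaceae;Pinus	Pinus	0.460	0	Pinus	0.226	0	Pinus	0.343	0
PC7	Salicaceae;Populus;Populus_tomentiglandulosa	0.5	Salicaceae;Populus	Populus	0.430	0	Populus	0.759	0	Populus	0.595	0
PC7	Paulowniaceae;Paulownia;Paulownia_tomentosa	0.1	Paulowniaceae;Paulownia	Paulownia	0.004	1	Paulownia	0.004	1	Paulownia	0.004	0
PC7	Anacardiaceae;Rhus;Rhus_chinensis	0.05	Anacardiaceae;Rhus;Rhus_chinensis	Rhus chinensis	0.042	0	Anacardiaceae	0.002	1	Rhus chinensis	0.022	1
PC7	Rutaceae;Zanthoxylum;Zanthoxylum_schinifolium	0.01	Rutaceae;Zanthoxylum	Zanthoxylum	0.006	1	Zanthoxylum	0.001	1	Zanthoxylum	0.003	0
PC7	Rosaceae;Prunus;Prunus_salicina	0.07	Rosaceae;Prunus	Prunus	0.001	1	Prunus mume	0.003	1	Prunus mume	0.002	1
PC7	Fabaceae;Robinia;Robinia_pseudoacacia	0.005	Fabaceae;Robinia;Robinia_pseudoacacia	Fabaceae	0.023	0	Robinia pseudoacacia	0.003	1	Robinia pseudoacacia	0.013	0
PC7	Simaroubaceae;Ailanthus;Ailanthus_altissima	0.02	Simaroubaceae;Ailanthus;Ailanthus_altissima	Ailanthus altissima	0.035	0	Ailanthus altissima	0.001	0	Ailanthus altissima	0.018	0
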