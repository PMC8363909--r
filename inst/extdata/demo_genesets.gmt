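HDL_MIR_SIGNATURE	synthetic HDL-associated miRNA signature	hsa-miR-451a	hsa-miR-sim-001	hsa-miR-sim-002	hsa-miR-sim-003	hsa-miR-sim-004	hsa-miR-sim-005	hsa-miR-sim-006	hsa-miR-sim-007	hsa-miR-sim-008	hsa-miR-sim-009
PLATELET_MIR_SIGNATURE	synthetic platelet-associated miRNA signature	hsa-miR-25-3p	hsa-miR-sim-010	hsa-miR-sim-011	hsa-miR-sim-012	hsa-miR-sim-013	hsa-miR-sim-014	hsa-miR-sim-015	hsa-miR-sim-016	hsa-miR-sim-017	hsa-miR-sim-018
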