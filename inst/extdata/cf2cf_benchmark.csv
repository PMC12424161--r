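entry_id,ligand_id,release_date,af3_rmsd_backbone,af3_rmsd_pocket,af3_rmsd_ligand,af3_rmsd_pal,vina_rmsd_ligand,vina_rmsd_pal,multiple_pfas
3RZ7_RZ7,RZ7,8/10/2011,0.02,0.01,0.04,0.06,0.19,0.68,FALSE
3RZ1_RZ1,RZ1,8/10/2011,0.02,0.01,0.09,0.10,0.21,0.59,FALSE
3RYZ_RYZ,RYZ,8/10/2011,0.03,0.01,0.06,0.07,0.16,0.18,FALSE
3RYX_RYX,RYX,8/10/2011,0.02,0.01,0.11,0.11,0.18,0.41,FALSE
4E99_P8S,P8S,6/6/2012,0.14,0.06,0.14,0.16,0.19,0.21,TRUE
4J03_FVS,FVS,6/5/2013,0.08,0.05,0.27,0.45,0.27,0.49,FALSE
5DDF_5A1,5A1,9/9/2015,0.11,0.02,0.12,0.13,0.17,0.95,FALSE
6VQF_R7V,R7V,4/8/2020,0.35,0.18,0.07,0.08,0.12,0.14,FALSE
6RZX_KPQ,KPQ,6/3/2020,0.02,0.01,0.02,0.03,0.03,0.27,FALSE
7JTM_VK7,VK7,9/16/2020,0.36,0.23,0.09,0.11,0.09,0.11,FALSE
7JYM_Z8I,Z8I,11/25/2020,0.26,0.15,0.06,0.07,0.12,0.16,FALSE
7AAI_8PF,8PF,2/24/2021,0.44,0.08,0.14,0.87,0.17,0.91,TRUE
7LUK_YDY,YDY,5/12/2021,0.45,0.22,0.09,0.13,0.12,0.17,FALSE
7FD7_4EI,4EI,7/20/2022,0.03,0.03,0.13,0.48,0.15,0.43,TRUE
7FEK_8PF,8PF,7/27/2022,0.03,0.02,0.17,0.30,0.18,0.57,TRUE
7FEU_4I6,4I6,7/27/2022,0.03,0.02,0.12,0.13,0.15,0.48,FALSE
7Z57_IGB,IGB,10/12/2022,0.46,0.10,0.13,0.22,0.14,0.28,TRUE
8U57_8PF,8PF,7/24/2024,0.54,0.22,0.16,0.80,0.16,0.83,TRUE
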