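"wavelength_nm","intensity"
540,0.00136
542,0.00173
544,0.00219
546,0.00276
548,0.00346
550,0.00432
552,0.00537
554,0.00665
556,0.00819
558,0.01005
560,0.01227
562,0.01492
564,0.01806
566,0.02177
568,0.02612
570,0.0312
572,0.03711
574,0.04394
576,0.05179
578,0.06078
580,0.07101
582,0.08259
584,0.09563
586,0.11025
588,0.12654
590,0.14458
592,0.16447
594,0.18627
596,0.21002
598,0.23575
600,0.26345
602,0.29311
604,0.32465
606,0.358
608,0.39302
610,0.42956
612,0.46741
614,0.50634
616,0.54607
618,0.58632
620,0.62674
622,0.66698
624,0.70665
626,0.74536
628,0.7827
630,0.81828
632,0.85167
634,0.8825
636,0.91038
638,0.93499
640,0.956
642,0.97314
644,0.98621
646,0.99501
648,0.99944
650,0.99944
652,0.99501
654,0.98621
656,0.97314
658,0.956
660,0.93499
662,0.91038
664,0.8825
666,0.85167
668,0.81828
670,0.7827
672,0.74536
674,0.70665
676,0.66698
678,0.62674
680,0.58632
682,0.54607
684,0.50634
686,0.46741
688,0.42956
690,0.39302
692,0.358
694,0.32465
696,0.29311
698,0.26345
700,0.23575
702,0.21002
704,0.18627
706,0.16447
708,0.14458
710,0.12654
712,0.11025
714,0.09563
716,0.08259
718,0.07101
720,0.06078
722,0.05179
724,0.04394
726,0.03711
728,0.0312
730,0.02612
732,0.02177
734,0.01806
736,0.01492
738,0.01227
740,0.01005
742,0.00819
744,0.00665
746,0.00537
748,0.00432
750,0.00346
752,0.00276
754,0.00219
756,0.00173
758,0.00136
760,0.00106
762,0.00083
764,0.00064
766,5e-04
768,0.00038
770,0.00029
772,0.00022
774,0.00017
776,0.00013
778,1e-04
780,7e-05
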