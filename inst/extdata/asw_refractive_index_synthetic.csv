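wavelength_nm,temperature_K,n2
400,100,1.289283
425,100,1.287142
450,100,1.285347
475,100,1.283829
500,100,1.282533
525,100,1.281417
550,100,1.28045
575,100,1.279606
600,100,1.278866
625,100,1.278213
650,100,1.277633
675,100,1.277117
700,100,1.276655
400,105,1.289033
425,105,1.286892
450,105,1.285097
475,105,1.283579
500,105,1.282283
525,105,1.281167
550,105,1.2802
575,105,1.279356
600,105,1.278616
625,105,1.277963
650,105,1.277383
675,105,1.276867
700,105,1.276405
400,110,1.288783
425,110,1.286642
450,110,1.284847
475,110,1.283329
500,110,1.282033
525,110,1.280917
550,110,1.27995
575,110,1.279106
600,110,1.278366
625,110,1.277713
650,110,1.277133
675,110,1.276617
700,110,1.276155
400,115,1.288533
425,115,1.286392
450,115,1.284597
475,115,1.283079
500,115,1.281783
525,115,1.280667
550,115,1.2797
575,115,1.278856
600,115,1.278116
625,115,1.277463
650,115,1.276883
675,115,1.276367
700,115,1.275905
400,120,1.288283
425,120,1.286142
450,120,1.284347
475,120,1.282829
500,120,1.281533
525,120,1.280417
550,120,1.27945
575,120,1.278606
600,120,1.277866
625,120,1.277213
650,120,1.276633
675,120,1.276117
700,120,1.275655
400,125,1.288033
425,125,1.285892
450,125,1.284097
475,125,1.282579
500,125,1.281283
525,125,1.280167
550,125,1.2792
575,125,1.278356
600,125,1.277616
625,125,1.276963
650,125,1.276383
675,125,1.275867
700,125,1.275405
400,130,1.287783
425,130,1.285642
450,130,1.283847
475,130,1.282329
500,130,1.281033
525,130,1.279917
550,130,1.27895
575,130,1.278106
600,130,1.277366
625,130,1.276713
650,130,1.276133
675,130,1.275617
700,130,1.275155
400,135,1.287533
425,135,1.285392
450,135,1.283597
475,135,1.282079
500,135,1.280783
525,135,1.279667
550,135,1.2787
575,135,1.277856
600,135,1.277116
625,135,1.276463
650,135,1.275883
675,135,1.275367
700,135,1.274905
400,140,1.287283
425,140,1.285142
450,140,1.283347
475,140,1.281829
500,140,1.280533
525,140,1.279417
550,140,1.27845
575,140,1.277606
600,140,1.276866
625,140,1.276213
650,140,1.275633
675,140,1.275117
700,140,1.274655
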