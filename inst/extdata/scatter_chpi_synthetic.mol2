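@<TRIPOS>MOLECULE
mifkit scatter
60 0 0 0 0
SMALL
NO_CHARGES

@<TRIPOS>ATOM
      1 C1         -0.4354     0.8179     3.4222 C.3     1  FRAG1
      2 C2          0.3594    -0.3227    -3.0513 C.3     1  FRAG1
      3 C3          0.0553     0.3095    -4.0533 C.3     1  FRAG1
      4 C4         -0.0392     0.1182     3.4963 C.3     1  FRAG1
      5 C5         -0.2102     0.4233    -3.2606 C.3     1  FRAG1
      6 C6         -0.2811    -0.2868     3.2011 C.3     1  FRAG1
      7 C7          0.4988     0.5590    -4.3958 C.3     1  FRAG1
      8 C8         -0.5526    -0.7700     4.1902 C.3     1  FRAG1
      9 C9         -0.0711    -0.2191     4.2113 C.3     1  FRAG1
     10 C10         0.1575    -0.0753     3.5945 C.3     1  FRAG1
     11 C11         0.6093     0.2595     3.7728 C.3     1  FRAG1
     12 C12        -0.3497     0.2938    -3.5529 C.3     1  FRAG1
     13 C13        -0.1427    -0.0397     3.6034 C.3     1  FRAG1
     14 C14        -0.6558    -0.5872     3.9713 C.3     1  FRAG1
     15 C15        -0.1955     0.1544     4.1211 C.3     1  FRAG1
     16 C16        -0.2008    -0.8019    -3.7597 C.3     1  FRAG1
     17 C17         0.6753     0.4956     3.7613 C.3     1  FRAG1
     18 C18         0.2956     0.5116    -3.2575 C.3     1  FRAG1
     19 C19         0.0503     0.4201     3.7601 C.3     1  FRAG1
     20 C20         0.4655     0.0600     2.6425 C.3     1  FRAG1
     21 C21        -0.1314    -0.2131    -4.7700 C.3     1  FRAG1
     22 C22        -0.0038     0.2295     3.8414 C.3     1  FRAG1
     23 C23         0.1836     0.3225     4.1893 C.3     1  FRAG1
     24 C24         0.8536     0.3058     2.9536 C.3     1  FRAG1
     25 C25         0.3619    -0.4446    -3.2921 C.3     1  FRAG1
     26 C26         0.2405     0.7719    -3.4720 C.3     1  FRAG1
     27 C27        -0.7839    -0.6209     3.9639 C.3     1  FRAG1
     28 C28         0.1591     0.5517     4.2621 C.3     1  FRAG1
     29 C29         0.0830     0.4914     3.6736 C.3     1  FRAG1
     30 C30        -0.4500     0.1522    -3.8993 C.3     1  FRAG1
     31 C31         0.0382    -0.7774    -2.5037 C.3     1  FRAG1
     32 C32         0.0796     0.7849     4.7636 C.3     1  FRAG1
     33 C33         0.2718     0.3442    -3.0326 C.3     1  FRAG1
     34 C34         0.3524    -0.0888     3.5046 C.3     1  FRAG1
     35 C35         0.1595     0.3646     3.8374 C.3     1  FRAG1
     36 C36         0.5546     0.7666    -3.8727 C.3     1  FRAG1
     37 C37         0.3846     0.2533     4.1278 C.3     1  FRAG1
     38 C38         0.5767     0.0167     3.8145 C.3     1  FRAG1
     39 C39         0.6303    -0.7338     2.6900 C.3     1  FRAG1
     40 C40         0.3503     0.5096     3.2540 C.3     1  FRAG1
     41 C41         0.2163    -0.2967    -4.5659 C.3     1  FRAG1
     42 C42        -0.4613     0.4062     4.2048 C.3     1  FRAG1
     43 C43        -0.3078     0.4331     3.4605 C.3     1  FRAG1
     44 C44        -0.4333     0.1842    -4.1479 C.3     1  FRAG1
     45 C45        -0.8198     0.5674    -3.6511 C.3     1  FRAG1
     46 C46        -0.6629    -0.3785     3.7785 C.3     1  FRAG1
     47 C47        -0.4445     0.2226     3.1588 C.3     1  FRAG1
     48 C48        -0.2788     0.4580    -3.6283 C.3     1  FRAG1
     49 C49        -0.0312     0.1349    -3.8905 C.3     1  FRAG1
     50 C50         1.2113     0.5038    -3.2780 C.3     1  FRAG1
     51 C51         0.1713    -0.7307    -2.5883 C.3     1  FRAG1
     52 C52         0.0021    -0.4374     4.0312 C.3     1  FRAG1
     53 C53         0.0146     0.0826    -3.6125 C.3     1  FRAG1
     54 C54        -0.1967     0.1036    -3.2997 C.3     1  FRAG1
     55 C55        -0.3964     0.2412     4.2082 C.3     1  FRAG1
     56 C56        -0.1559    -0.0358     3.0117 C.3     1  FRAG1
     57 C57        -0.1730    -0.4445    -3.9047 C.3     1  FRAG1
     58 C58        -0.1523     0.2430    -3.4064 C.3     1  FRAG1
     59 C59        -0.8929     0.1702    -4.2996 C.3     1  FRAG1
     60 C60         0.2936    -0.5490    -2.9838 C.3     1  FRAG1
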